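#' Simulate a transwell transport assay
#'
#' Generates receiver-concentration measurements for a monolayer transport
#' experiment. The latent state follows the exact two-compartment diffusion
#' model `dQ/dt = Papp * A * (C_apical - C_receiver)` (no sink
#' approximation), solved in closed form between sampling events; each
#' sampling event withdraws `sample_volume` from the receiver and replaces it
#' with blank buffer, diluting the receiver by `(V - Vs)/V`. Multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` is applied to the
#' measured concentrations only -- the latent state conserves mass exactly,
#' so the estimator's sink-condition bias is measurable.
#'
#' @param true_papp True apparent permeability, cm/s (>= 0).
#' @param protocol An [assay_protocol()].
#' @param noise_cv Measurement noise coefficient of variation (fraction).
#' @param seed Integer seed; the generator is a pure function of
#'   `(parameters, seed)`.
#' @return Tibble with columns `replicate`, `time_min`, `receiver_conc`
#'   (umol/cm^3). Attributes: `true_papp`, `protocol`, `latent` (noise-free
#'   concentrations), `final_apical_conc`, `withdrawn_umol`, and
#'   `mass_balance` (apical + receiver + withdrawn amount, umol, equal to the
#'   initial load).
#' @export
generate_caco2_assay <- function(true_papp, protocol = assay_protocol(),
                                 noise_cv = 0, seed = 1L) {
  check_nonnegative(true_papp, "true_papp")
  check_nonnegative(noise_cv, "noise_cv")
  p <- protocol
  times_s <- p$sample_times * 60
  k <- true_papp * p$area * (1 / p$apical_volume + 1 / p$receiver_volume)
  ca <- p$donor_c0
  cr <- 0
  withdrawn <- 0
  latent <- numeric(length(times_s))
  for (i in seq_along(times_s)) {
    if (i > 1L) {
      dt <- times_s[i] - times_s[i - 1]
      ceq <- (p$apical_volume * ca + p$receiver_volume * cr) /
        (p$apical_volume + p$receiver_volume)
      dif <- (ca - cr) * exp(-k * dt)
      cr <- ceq - dif * p$apical_volume / (p$apical_volume + p$receiver_volume)
      ca <- ceq + dif * p$receiver_volume / (p$apical_volume + p$receiver_volume)
    }
    latent[i] <- cr
    withdrawn <- withdrawn + cr * p$sample_volume
    cr <- cr * (p$receiver_volume - p$sample_volume) / p$receiver_volume
  }
  n_t <- length(times_s)
  meas <- withr::with_seed(seed, {
    noise <- matrix(rnorm(p$replicates * n_t, mean = 1, sd = noise_cv),
                    nrow = p$replicates)
    sweep(noise, 2, latent, `*`)
  })
  meas[meas < 0] <- 0
  out <- tidyr::expand_grid(replicate = seq_len(p$replicates),
                            time_min = p$sample_times) |>
    dplyr::mutate(receiver_conc = as.vector(t(meas)))
  attr(out, "true_papp") <- true_papp
  attr(out, "protocol") <- p
  attr(out, "latent") <- tibble(time_min = p$sample_times,
                                receiver_conc = latent)
  attr(out, "final_apical_conc") <- ca
  attr(out, "withdrawn_umol") <- withdrawn
  attr(out, "mass_balance") <- ca * p$apical_volume + cr * p$receiver_volume +
    withdrawn
  out
}

#' Draw a random virtual drug
#'
#' Samples permeability, solubility, clearance and central volume from wide
#' log-uniform / uniform ranges around the oral-drug space; all other fields
#' default to the packaged gemcitabine values. Reproducible given `seed`.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(lo, hi)` ranges for `peff_jejunal`
#'   (log-uniform, cm/s), `solubility` (log-uniform, mg/mL), `clearance`
#'   (uniform, L/h) and `vc_per_kg` (uniform, L/kg).
#' @return A `drug_parameters` object.
#' @export
generate_virtual_drug <- function(seed = 1L,
                                  ranges = list(peff_jejunal = c(1e-6, 1e-3),
                                                solubility = c(0.01, 100),
                                                clearance = c(1, 200),
                                                vc_per_kg = c(0.1, 5))) {
  draw <- withr::with_seed(seed, list(
    peff_jejunal = 10^runif(1, log10(ranges$peff_jejunal[1]),
                            log10(ranges$peff_jejunal[2])),
    solubility = 10^runif(1, log10(ranges$solubility[1]),
                          log10(ranges$solubility[2])),
    clearance = runif(1, ranges$clearance[1], ranges$clearance[2]),
    vc_per_kg = runif(1, ranges$vc_per_kg[1], ranges$vc_per_kg[2])
  ))
  gemcitabine_parameters(
    name = sprintf("virtual_%d", seed), peff_jejunal = draw$peff_jejunal,
    solubility = draw$solubility, clearance = draw$clearance,
    vc_per_kg = draw$vc_per_kg
  )
}

#' Permeability parameter-recovery experiment
#'
#' Generates `n_seeds` synthetic assays at a known true permeability, runs
#' the estimator on each, and summarises recovery quality.
#'
#' @param n_seeds Number of simulated assays.
#' @param true_papp True apparent permeability, cm/s.
#' @param noise_cv Measurement noise CV.
#' @param protocol An [assay_protocol()].
#' @return One-row tibble: `median_rel_error` (median |est - true| / true),
#'   `rel_rmse`, `bias` (mean relative error, signed), `n_seeds`, plus the
#'   per-seed estimates as a list column `estimates`.
#' @export
papp_recovery_experiment <- function(n_seeds, true_papp, noise_cv = 0.05,
                                     protocol = assay_protocol()) {
  stopifnot(n_seeds >= 1)
  est <- purrr::map_dbl(seq_len(n_seeds), function(s) {
    assay <- generate_caco2_assay(true_papp, protocol, noise_cv, seed = s)
    suppressWarnings(estimate_papp(assay, protocol)$papp)
  })
  rel <- est / true_papp - 1
  tibble(median_rel_error = median(abs(rel)),
         rel_rmse = sqrt(mean(rel^2)),
         bias = mean(rel),
         n_seeds = n_seeds,
         noise_cv = noise_cv,
         estimates = list(est))
}
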