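#' Noyes-Whitney dissolution rate
#'
#' Rate at which solid drug dissolves in a lumen compartment,
#' `rate = (3 D / (rho r^2)) * undissolved * (Cs - C)`, floored at zero when
#' the dissolved concentration has reached saturation (supersaturation is
#' handled by [precipitation_rate()]). Units are reconciled internally: the
#' diffusion coefficient is in cm^2/s, the particle radius in um and the
#' density in g/mL; the result is mg/h.
#'
#' @param undissolved Undissolved mass, mg.
#' @param dissolved_conc Dissolved concentration in the compartment, mg/mL.
#' @param drug A [drug_parameters()] object (uses `diffusion_coefficient`,
#'   `particle_density`, `particle_radius`, `solubility`).
#' @return Dissolution rate, mg/h.
#' @export
dissolution_rate <- function(undissolved, dissolved_conc, drug) {
  check_nonnegative(undissolved, "undissolved")
  check_nonnegative(dissolved_conc, "dissolved_conc")
  kd <- dissolution_coefficient(drug)
  kd * undissolved * pmax(drug$solubility - dissolved_conc, 0)
}

# 3 D / (rho r^2) in mL/(mg h): D cm^2/s -> cm^2/h, rho g/mL -> mg/mL,
# r um -> cm
dissolution_coefficient <- function(drug) {
  3 * drug$diffusion_coefficient * 3600 /
    ((drug$particle_density * 1000) * (drug$particle_radius * 1e-4)^2)
}

#' Precipitation rate of supersaturated drug
#'
#' When the dissolved concentration exceeds saturation, the excess dissolved
#' mass returns to the (re-dissolvable) solid pool first-order with the mean
#' precipitation time: `rate = (C - Cs) * V / tau`.
#'
#' @param dissolved_conc Dissolved concentration, mg/mL.
#' @param cs Saturation solubility, mg/mL.
#' @param volume Compartment fluid volume, mL.
#' @param mean_precipitation_time Mean precipitation time, seconds.
#' @return Precipitation rate, mg/h (0 when not supersaturated).
#' @export
precipitation_rate <- function(dissolved_conc, cs, volume,
                               mean_precipitation_time) {
  check_nonnegative(dissolved_conc, "dissolved_conc")
  check_positive(mean_precipitation_time, "mean_precipitation_time")
  tau_h <- mean_precipitation_time / 3600
  pmax(dissolved_conc - cs, 0) * volume / tau_h
}

#' First-order absorption rate constant of a GI compartment
#'
#' Classical transit-model relation `ka = 2 Peff ASF / R`: permeation across
#' the wall of a cylinder of radius R, scaled by the compartment's absorption
#' scale factor, converted to 1/h.
#'
#' @param drug A [drug_parameters()] object (uses `peff_jejunal`, cm/s).
#' @param compartment One physiology row (list or one-row tibble) with
#'   `radius_cm` and `asf`.
#' @return Absorption rate constant, 1/h.
#' @export
absorption_rate_constant <- function(drug, compartment) {
  check_positive(compartment$radius_cm, "radius_cm")
  2 * drug$peff_jejunal * 3600 * compartment$asf / compartment$radius_cm
}

solver_control <- function(control = list()) {
  modifyList(list(dt_out = 0.01, n_sub = NULL, egut = 0, ehep = 0,
                  kdiss_max = 500, mass_balance_tol = 1e-3), control)
}

# Core engine: oral doses into the lumen chain plus central disposition.
acat_simulate <- function(drug, subject, physiology, dose_times, dose_amounts,
                          dose_volume, sim_duration, predissolved = FALSE,
                          control = list()) {
  validate_physiology(physiology)
  ctl <- solver_control(control)
  n <- nrow(physiology)
  transit_k <- 1 / physiology$transit_h
  ka <- 2 * drug$peff_jejunal * 3600 * physiology$asf / physiology$radius_cm
  kd <- dissolution_coefficient(drug)
  vc <- drug$vc_per_kg * subject$body_mass
  kel <- drug$clearance / vc
  tau_p <- drug$mean_precipitation_time / 3600

  dose_steps <- dose_times / ctl$dt_out
  if (any(abs(dose_steps - round(dose_steps)) > 1e-8))
    stop_validation("dose times must fall on the output grid.")
  dose_steps <- as.integer(round(dose_steps))
  n_out <- as.integer(round(sim_duration / ctl$dt_out))
  if (any(dose_steps < 0L | dose_steps > n_out))
    stop_validation("dose times must lie within [0, sim_duration].")

  # substep count from the fastest active rate constant (RK4 stability)
  rates <- c(transit_k, ka, kel, 1 / tau_p)
  max_conc <- sum(dose_amounts) / min(physiology$volume_ml)
  if (!predissolved || max_conc > drug$solubility)
    rates <- c(rates, min(kd * drug$solubility, ctl$kdiss_max))
  n_sub <- ctl$n_sub %||% min(500L, max(1L, ceiling(ctl$dt_out * max(rates) / 0.2)))

  res <- cpp_acat_simulate(
    transit_k, physiology$volume_ml, ka, kd, ctl$kdiss_max, drug$solubility,
    tau_p, kel,
    ctl$egut, ctl$ehep, dose_steps, dose_amounts,
    rep_len(dose_volume, length(dose_amounts)), predissolved, ctl$dt_out,
    n_out, as.integer(n_sub)
  )
  states <- res$states
  times <- seq(0, sim_duration, by = ctl$dt_out)
  dose_total <- sum(dose_amounts)

  # lumen-frame mass balance at every output time
  administered <- vapply(seq_len(n_out + 1L) - 1L,
                         function(j) sum(dose_amounts[dose_steps <= j]), 0)
  total <- rowSums(states[, 1:(3 * n), drop = FALSE]) + states[, 3 * n + 1]
  drift <- max(abs(total - administered))
  if (drift > ctl$mass_balance_tol * dose_total)
    abort(sprintf("lumen mass-balance drift %.3g mg exceeds %.3g%% of dose.",
                  drift, 100 * ctl$mass_balance_tol),
          class = "acatpk_solver_error")

  absorbed <- states[n_out + 1L, (2 * n + 1):(3 * n)]
  fa <- sum(absorbed) / dose_total
  fdp <- fa * (1 - ctl$egut)
  f <- fdp * (1 - ctl$ehep)
  structure(
    list(times = times, conc = states[, 3 * n + 2] / vc,
         portal_flux = res$portal, states = states,
         compartments = physiology$compartment,
         fa = fa, fdp = fdp, f = f,
         per_compartment_absorbed = setNames(absorbed, physiology$compartment),
         excreted = states[n_out + 1L, 3 * n + 1],
         dose_total = dose_total, dose_times = dose_times,
         dose_amounts = dose_amounts, vc = vc,
         mass_balance_drift = drift, n_sub = n_sub,
         drug = drug, subject = subject, physiology = physiology,
         control = ctl),
    class = "acat_simulation"
  )
}

#' Simulate a single oral dose through the gut model
#'
#' Deposits the dose as undissolved drug in the stomach at time zero
#' (together with `dose_volume` of fluid, which empties first-order with
#' gastric transit), then integrates transit, dissolution, precipitation and
#' permeability-limited absorption along the GI tract, coupled to
#' one-compartment systemic disposition. The stomach never absorbs; mass
#' leaving the last compartment is excreted.
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology A [default_human_physiology()]-style table.
#' @param dose Dose, mg.
#' @param dose_volume Co-administered fluid volume, mL (default 250).
#' @param sim_duration Simulation horizon, h.
#' @param subject A [subject_parameters()] object.
#' @param predissolved Deposit the dose as already-dissolved drug (used by
#'   closed-form transit-chain oracles and linearity checks).
#' @param control Solver options: `dt_out` (output grid step, default 0.01 h),
#'   `n_sub` (RK4 substeps per output step; default chosen from the fastest
#'   rate constant), `egut`/`ehep` (gut and hepatic extraction fractions,
#'   default 0), `kdiss_max` (cap on the effective dissolution rate constant,
#'   1/h, default 500 -- a half-time of ~5 s, i.e. numerically instantaneous;
#'   keeps very fine particles from forcing needlessly small steps),
#'   `mass_balance_tol` (relative drift tolerance, default 1e-3).
#' @return An `acat_simulation` object; see [pk_profile()], [glance()],
#'   [tidy()], [regional_absorption_fractions()].
#' @examples
#' \donttest{
#' sim <- simulate_oral_dose(gemcitabine_parameters(),
#'                           default_human_physiology(), dose = 1000)
#' sim$fa
#' }
#' @export
simulate_oral_dose <- function(drug, physiology, dose, dose_volume = 250,
                               sim_duration = 24,
                               subject = subject_parameters(),
                               predissolved = FALSE, control = list()) {
  check_positive(dose, "dose")
  check_positive(dose_volume, "dose_volume")
  acat_simulate(drug, subject, physiology, dose_times = 0,
                dose_amounts = dose, dose_volume = dose_volume,
                sim_duration = sim_duration, predissolved = predissolved,
                control = control)
}

#' Regional distribution of absorbed drug
#'
#' @param sim An `acat_simulation`.
#' @return Tibble with `compartment`, `absorbed_mg`, `fraction` (of total
#'   absorbed; sums to 1) and `pct_dose`.
#' @export
regional_absorption_fractions <- function(sim) {
  stopifnot(inherits(sim, "acat_simulation"))
  if (sim$fa <= 0)
    stop_validation("no drug was absorbed: regional distribution undefined.")
  abs_mg <- sim$per_compartment_absorbed
  tibble(compartment = names(abs_mg), absorbed_mg = unname(abs_mg),
         fraction = unname(abs_mg) / sum(abs_mg),
         pct_dose = 100 * unname(abs_mg) / sim$dose_total)
}

#' Calibrate colonic absorption scale factors against a target Fa
#'
#' The small-intestinal absorption scale factors are held at their input
#' values while a single multiplier on the colonic (non-small-intestine,
#' non-stomach) ASFs is found by bisection so the simulated fraction absorbed
#' matches `target_fa`. If the target lies outside the range attainable with
#' a colonic multiplier in [0, 1], a global multiplier on all absorbing
#' compartments is additionally fitted. The result is recorded in the
#' returned physiology's `calibration` attribute.
#'
#' @param physiology A `gi_physiology` table (first argument so calibrated
#'   tables pipe onward).
#' @param drug,subject Model parameters.
#' @param target_fa Target fraction absorbed, in (0, 1).
#' @param dose,dose_volume,sim_duration Calibration regimen (defaults: a
#'   single 1000 mg dose in 250 mL over 24 h).
#' @param tol Absolute Fa tolerance (default 1e-3).
#' @param control Solver options, as in [simulate_oral_dose()].
#' @return The physiology with scaled `asf` and a `calibration` attribute
#'   (`colon_multiplier`, `global_multiplier`, `achieved_fa`, `target_fa`).
#' @export
calibrate_asf <- function(physiology, drug, subject = subject_parameters(),
                          target_fa, dose = 1000, dose_volume = 250,
                          sim_duration = 24, tol = 1e-3, control = list()) {
  check_fraction(target_fa, "target_fa", hi = 1 - 1e-12)
  validate_physiology(physiology)
  si <- attr(physiology, "small_intestine")
  colonic <- setdiff(physiology$compartment[-1], si)
  base_asf <- physiology$asf

  fa_of <- function(colon_m, global_m = 1) {
    asf <- base_asf * global_m
    asf[physiology$compartment %in% colonic] <-
      base_asf[physiology$compartment %in% colonic] * colon_m * global_m
    phys <- physiology
    phys$asf <- asf
    sim <- simulate_oral_dose(drug, phys, dose, dose_volume, sim_duration,
                              subject, control = control)
    sim$fa
  }

  bisect <- function(f, lo, hi, flo, fhi) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target_fa) < tol) return(list(x = mid, fa = fm))
      if ((fm < target_fa) == (flo < target_fa)) {
        lo <- mid; flo <- fm
      } else {
        hi <- mid; fhi <- fm
      }
    }
    list(x = mid, fa = fm)
  }

  f0 <- fa_of(0); f1 <- fa_of(1)
  colon_m <- 1; global_m <- 1
  if (abs(f1 - target_fa) < tol) {
    res <- list(x = 1, fa = f1)
  } else if (abs(f0 - target_fa) < tol) {
    res <- list(x = 0, fa = f0)
    colon_m <- 0
  } else if (target_fa >= min(f0, f1) && target_fa <= max(f0, f1)) {
    res <- bisect(function(m) fa_of(m), 0, 1, f0, f1)
    colon_m <- res$x
  } else if (target_fa > f1) {
    g_hi <- 1; f_hi <- f1
    while (f_hi < target_fa && g_hi < 64) {
      g_hi <- g_hi * 2
      f_hi <- fa_of(1, g_hi)
    }
    if (f_hi < target_fa)
      abort(sprintf(
        "target Fa %.4f unreachable: attainable range is [%.4f, %.4f].",
        target_fa, f0, f_hi), class = "acatpk_calibration_error")
    res <- bisect(function(g) fa_of(1, g), 1, g_hi, f1, f_hi)
    global_m <- res$x
  } else {
    res <- bisect(function(g) fa_of(0, g), 0, 1, fa_of(0, 0), f0)
    colon_m <- 0
    global_m <- res$x
  }
  if (abs(res$fa - target_fa) > 10 * tol)
    abort(sprintf(
      "calibration did not converge: achieved Fa %.4f for target %.4f.",
      res$fa, target_fa), class = "acatpk_calibration_error")

  asf <- base_asf * global_m
  asf[physiology$compartment %in% colonic] <-
    base_asf[physiology$compartment %in% colonic] * colon_m * global_m
  out <- physiology
  out$asf <- asf
  attr(out, "calibration") <- list(
    colon_multiplier = colon_m, global_multiplier = global_m,
    achieved_fa = res$fa, target_fa = target_fa, dose = dose,
    dose_volume = dose_volume, sim_duration = sim_duration)
  out
}

#' @export
print.acat_simulation <- function(x, ...) {
  cat(sprintf(
    "<acat_simulation> %s: %g mg x %d, Fa %.1f%%, FDp %.1f%%, F %.1f%%\n",
    x$drug$name, x$dose_amounts[1], length(x$dose_amounts), 100 * x$fa,
    100 * x$fdp, 100 * x$f))
  invisible(x)
}

#' Lumen trajectory of a simulation, tidy format
#'
#' @param x An `acat_simulation`.
#' @param ... Unused.
#' @return Tibble with `time_h`, `compartment`, `pool` (`undissolved`,
#'   `dissolved`, `absorbed`) and `mass_mg`.
#' @export
tidy.acat_simulation <- function(x, ...) {
  n <- length(x$compartments)
  pools <- c("undissolved", "dissolved", "absorbed")
  purrr::map_dfr(seq_along(pools), function(p) {
    block <- x$states[, ((p - 1) * n + 1):(p * n), drop = FALSE]
    colnames(block) <- x$compartments
    as_tibble(block) |>
      dplyr::mutate(time_h = x$times, pool = pools[p]) |>
      tidyr::pivot_longer(-c("time_h", "pool"), names_to = "compartment",
                          values_to = "mass_mg")
  }) |>
    dplyr::select("time_h", "compartment", "pool", "mass_mg")
}

#' @rdname summarize_regimen
#' @export
glance.acat_simulation <- function(x, ...) summarize_regimen(x, ...)
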