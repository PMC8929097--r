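#' Default transwell assay protocol
#'
#' Geometry and sampling schedule of the packaged monolayer transport
#' protocol: 60 uM apical donor (0.06 umol/mL), 0.4 mL apical and 1.2 mL
#' basolateral volumes, a 0.6 mL basolateral sample withdrawn and replaced
#' with buffer every 30 min for 2 h, filter growth area 1.12 cm^2 (the
#' nominal area of a 12 mm insert), four replicates.
#'
#' @param ... Named overrides of any protocol field.
#' @return An `assay_protocol` list.
#' @export
assay_protocol <- function(...) {
  proto <- list(donor_c0 = 0.06, apical_volume = 0.4, receiver_volume = 1.2,
                sample_volume = 0.6, sample_times = c(0, 30, 60, 90, 120),
                area = 1.12, replicates = 4L)
  proto <- modifyList(proto, list(...))
  check_positive(proto$donor_c0, "donor_c0")
  check_positive(proto$area, "area")
  check_positive(proto$apical_volume, "apical_volume")
  check_positive(proto$receiver_volume, "receiver_volume")
  check_nonnegative(proto$sample_volume, "sample_volume")
  if (proto$sample_volume > proto$receiver_volume)
    stop_validation("`sample_volume` cannot exceed `receiver_volume`.")
  structure(proto, class = "assay_protocol")
}

#' Cumulative amount transported into the receiver compartment
#'
#' Corrects receiver concentrations for repeated sampling with buffer
#' replacement: the amount present at sample n is the current concentration
#' times the receiver volume plus everything carried away in earlier samples,
#' `Q_n = C_n * V_receiver + sum_{i<n} C_i * V_sample`.
#'
#' @param receiver_conc Receiver concentrations at successive sample times
#'   (amount per mL; the result is in the matching amount unit).
#' @param receiver_volume Receiver chamber volume, mL.
#' @param sample_volume Volume withdrawn (and replaced) at each sample, mL.
#' @return Cumulative transported amount per sample time.
#' @examples
#' cumulative_transported(c(1, 1), 1.2, 0.6) # 1.2, 1.8
#' @export
cumulative_transported <- function(receiver_conc, receiver_volume,
                                   sample_volume) {
  if (!length(receiver_conc)) stop_validation("empty concentration series.")
  check_nonnegative(receiver_conc, "receiver_conc")
  check_positive(receiver_volume, "receiver_volume")
  check_nonnegative(sample_volume, "sample_volume")
  if (sample_volume > receiver_volume)
    stop_validation("`sample_volume` cannot exceed `receiver_volume`.")
  withdrawn <- c(0, cumsum(receiver_conc * sample_volume)[-length(receiver_conc)])
  receiver_conc * receiver_volume + withdrawn
}

#' Transport flux by ordinary least squares
#'
#' Slope (free intercept) of cumulative transported amount against time over
#' all sample points -- robust to a short lag phase; the fit quality is
#' reported as r^2.
#'
#' @param times Sample times (seconds for a flux in amount/s).
#' @param cumulative Cumulative transported amount at each time.
#' @return A list with `flux` (slope) and `r_squared`.
#' @export
linear_flux <- function(times, cumulative) {
  if (length(times) != length(cumulative))
    stop_validation("`times` and `cumulative` lengths differ.")
  if (length(unique(times)) < 2L)
    stop_validation("need at least 2 distinct time points.")
  tc <- times - mean(times)
  slope <- sum(tc * (cumulative - mean(cumulative))) / sum(tc^2)
  ss_tot <- sum((cumulative - mean(cumulative))^2)
  ss_res <- sum((cumulative - mean(cumulative) - slope * tc)^2)
  list(flux = slope,
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

#' Apparent permeability
#'
#' `Papp = (dQ/dt) / (C0 * A)`: transport flux normalised by the initial
#' donor concentration and the filter area.
#'
#' @param flux Transport rate dQ/dt, umol/s.
#' @param donor_c0 Initial donor (apical) concentration, umol/cm^3.
#' @param area Filter area, cm^2.
#' @return Apparent permeability, cm/s.
#' @examples
#' apparent_permeability(6.72e-7, 0.06, 1.12) # 1e-5 cm/s
#' @export
apparent_permeability <- function(flux, donor_c0, area) {
  check_positive(donor_c0, "donor_c0")
  check_positive(area, "area")
  flux / (donor_c0 * area)
}

#' Estimate apparent permeability from a transwell assay table
#'
#' Applies the sampling correction ([cumulative_transported()]), fits the
#' flux per replicate and on the replicate-mean curve, and converts to
#' apparent permeability. Warns when the receiver concentration exceeds 10%
#' of the donor concentration at any sampled time (sink condition violated).
#'
#' @param assay Tibble with columns `replicate`, `time_min` and
#'   `receiver_conc` (umol/cm^3), e.g. from [generate_caco2_assay()].
#' @param protocol An [assay_protocol()] describing geometry and volumes.
#' @return A `papp_estimate` object: list with `papp` (mean over replicates,
#'   cm/s), `sem`, `flux` (umol/s, mean-curve fit), `r_squared`,
#'   `per_replicate` tibble.
#' @export
estimate_papp <- function(assay, protocol = assay_protocol()) {
  req <- c("replicate", "time_min", "receiver_conc")
  if (!all(req %in% names(assay)))
    stop_validation(paste("assay table needs columns:",
                          paste(req, collapse = ", ")))
  if (any(assay$receiver_conc > 0.1 * protocol$donor_c0))
    warn("receiver concentration exceeds 10% of donor: sink condition violated.")
  per_rep <- assay |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      papp = {
        q <- cumulative_transported(.data$receiver_conc,
                                    protocol$receiver_volume,
                                    protocol$sample_volume)
        ft <- linear_flux(.data$time_min * 60, q)
        apparent_permeability(ft$flux, protocol$donor_c0, protocol$area)
      },
      .groups = "drop"
    )
  mean_curve <- assay |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(receiver_conc = mean(.data$receiver_conc),
                     .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  q <- cumulative_transported(mean_curve$receiver_conc,
                              protocol$receiver_volume,
                              protocol$sample_volume)
  ft <- linear_flux(mean_curve$time_min * 60, q)
  n <- nrow(per_rep)
  structure(
    list(papp = mean(per_rep$papp),
         sem = if (n > 1L) stats::sd(per_rep$papp) / sqrt(n) else NA_real_,
         flux = ft$flux, r_squared = ft$r_squared,
         per_replicate = per_rep, protocol = protocol),
    class = "papp_estimate"
  )
}

#' Compartment recovery percentages
#'
#' Expresses transport as percentage of the apical load recovered in the
#' basolateral compartment over time and, when a final apical concentration
#' is available, the percentage remaining apically.
#'
#' @param assay Assay tibble as in [estimate_papp()] (replicate-mean taken).
#' @param protocol An [assay_protocol()].
#' @param final_apical_conc Optional final apical concentration, umol/cm^3.
#' @return Tibble with `time_min`, `basolateral_pct` and (constant)
#'   `apical_pct` (NA when no final apical sample was taken).
#' @export
recovery_percent <- function(assay, protocol = assay_protocol(),
                             final_apical_conc = NULL) {
  load_umol <- protocol$donor_c0 * protocol$apical_volume
  mean_curve <- assay |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(receiver_conc = mean(.data$receiver_conc),
                     .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  q <- cumulative_transported(mean_curve$receiver_conc,
                              protocol$receiver_volume,
                              protocol$sample_volume)
  apical_pct <- if (is.null(final_apical_conc)) NA_real_ else
    100 * final_apical_conc * protocol$apical_volume / load_umol
  tibble(time_min = mean_curve$time_min,
         basolateral_pct = 100 * q / load_umol,
         apical_pct = apical_pct)
}

#' Map apparent permeability to effective jejunal permeability
#'
#' A log10-linear map `log10 Peff = a + b * log10 Papp`. The default is a
#' pure scale (`b = 1`) calibrated so that an apparent permeability of
#' 5.8e-6 cm/s maps to the effective jejunal permeability 0.59e-4 cm/s used
#' by the packaged gemcitabine model.
#'
#' @param papp Apparent permeability, cm/s (> 0).
#' @param coefficients Numeric `c(a, b)` in log10 space.
#' @return Effective jejunal permeability, cm/s.
#' @export
papp_to_peff <- function(papp,
                         coefficients = c(log10(0.59e-4 / 5.8e-6), 1)) {
  if (any(papp <= 0)) stop_validation("`papp` must be > 0.")
  10^(coefficients[1] + coefficients[2] * log10(papp))
}

#' @export
print.papp_estimate <- function(x, ...) {
  cat(sprintf("<papp_estimate> Papp = %.3g cm/s (SEM %.2g, n = %d), r2 = %.4f\n",
              x$papp, x$sem, nrow(x$per_replicate), x$r_squared))
  invisible(x)
}

#' @rdname estimate_papp
#' @param x A `papp_estimate` object.
#' @param ... Unused.
#' @export
tidy.papp_estimate <- function(x, ...) x$per_replicate

#' @rdname estimate_papp
#' @export
glance.papp_estimate <- function(x, ...) {
  tibble(papp = x$papp, sem = x$sem, flux = x$flux, r_squared = x$r_squared,
         n_replicates = nrow(x$per_replicate),
         peff_mapped = papp_to_peff(x$papp))
}
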