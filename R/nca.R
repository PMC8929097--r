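check_profile <- function(profile) {
  if (!is.data.frame(profile) || !all(c("time_h", "conc") %in% names(profile)))
    stop_validation("`profile` must have columns `time_h` and `conc`.")
  if (!nrow(profile)) stop_validation("empty profile.")
  invisible(profile)
}

#' Maximum concentration and its time
#'
#' @param profile Data frame with `time_h` and `conc` columns. Ties are
#'   broken by the earliest time.
#' @return Named list `cmax` (mg/L) and `tmax` (h).
#' @export
cmax_tmax <- function(profile) {
  check_profile(profile)
  i <- which.max(profile$conc)
  list(cmax = profile$conc[i], tmax = profile$time_h[i])
}

#' Area under the curve by the linear trapezoidal rule
#'
#' Linear (not log-linear) trapezoids on the profile grid: exactly additive
#' over subintervals, with negligible integration error on a dense grid.
#'
#' @param profile Data frame with `time_h` and `conc`.
#' @param t_end Upper integration limit, h (default: last grid time; must not
#'   exceed it).
#' @return AUC in concentration x h units (ug.h/mL for mg/L profiles, since
#'   mg/L = ug/mL).
#' @export
auc_trapezoid <- function(profile, t_end = max(profile$time_h)) {
  check_profile(profile)
  if (t_end > max(profile$time_h) + 1e-9)
    stop_validation("`t_end` lies beyond the profile grid.")
  keep <- profile$time_h <= t_end + 1e-9
  t <- profile$time_h[keep]
  c_ <- profile$conc[keep]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
}

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear ordinary least squares over the terminal window of the
#' profile; `lambda_z` is minus the slope. The window must be free of dosing
#' events and contain at least three positive concentrations; a constant
#' profile returns 0.
#'
#' @param profile Data frame with `time_h` and `conc`; dosing times are read
#'   from the profile's `dosing_times` attribute unless supplied.
#' @param window Window length, h, counted back from the last grid time
#'   (default 2).
#' @param dosing_times Optional dosing-event times, h.
#' @return lambda_z, 1/h.
#' @export
terminal_lambda_z <- function(profile, window = 2,
                              dosing_times = attr(profile, "dosing_times")) {
  check_profile(profile)
  t_last <- max(profile$time_h)
  keep <- profile$time_h >= t_last - window - 1e-9
  t <- profile$time_h[keep]
  c_ <- profile$conc[keep]
  if (!is.null(dosing_times) &&
      any(dosing_times >= t_last - window - 1e-9 & dosing_times <= t_last))
    stop_validation("terminal window contains a dosing event.")
  if (sum(c_ > 0) < 3L)
    stop_validation("terminal window needs >= 3 positive concentrations.")
  if (max(c_) == min(c_)) return(0)
  if (any(c_ <= 0))
    stop_validation("non-positive concentrations in the terminal window.")
  -unname(coef(lm(log(c_) ~ t))[2])
}

#' AUC extrapolated to infinity
#'
#' `AUC0-inf = AUC0-tlast + C_last / lambda_z`.
#'
#' @inheritParams terminal_lambda_z
#' @return List: `auc_0_inf`, `auc_0_t`, `lambda_z`, `extrapolated_fraction`.
#' @export
auc_infinity <- function(profile, window = 2,
                         dosing_times = attr(profile, "dosing_times")) {
  check_profile(profile)
  lz <- terminal_lambda_z(profile, window, dosing_times)
  if (lz <= 0) stop_validation("lambda_z must be > 0 to extrapolate.")
  auc_t <- auc_trapezoid(profile)
  c_last <- profile$conc[which.max(profile$time_h)]
  tail_auc <- c_last / lz
  list(auc_0_inf = auc_t + tail_auc, auc_0_t = auc_t, lambda_z = lz,
       extrapolated_fraction = tail_auc / (auc_t + tail_auc))
}

#' Accumulation index for repeated dosing
#'
#' `R = 1 / (1 - e^{-k tau})`: ratio of steady-state to single-dose exposure
#' for first-order elimination with rate `k` and dosing interval `tau`.
#'
#' @param k Elimination rate constant, 1/h.
#' @param tau Dosing interval, h.
#' @return Accumulation index (>= 1).
#' @export
accumulation_index <- function(k, tau) {
  check_positive(k, "k")
  check_positive(tau, "tau")
  1 / (1 - exp(-k * tau))
}

#' Noncompartmental summary of a simulated regimen
#'
#' Assembles a one-row summary (fraction absorbed, fraction reaching the
#' portal vein, bioavailability, Cmax, Tmax, AUC to end of simulation and to
#' infinity, terminal slope and accumulation index) from a simulation. For
#' IV regimens the absorption fractions are 100% by definition. The
#' accumulation index is evaluated at the disposition rate constant
#' `k = CL/V` (the lumen can still carry drug across dosing intervals; see
#' the vignette) and is `NA` for single doses.
#'
#' @param x An `acat_simulation` or an IV `pk_profile`.
#' @param ... Passed on (`window` for the terminal fit).
#' @return One-row tibble with columns `route`, `dose_mg`, `n_doses`,
#'   `interval_h`, `fa_pct`, `fdp_pct`, `f_pct`, `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf`, `lambda_z`, `accumulation_index`.
#' @export
summarize_regimen <- function(x, ...) UseMethod("summarize_regimen")

nca_row <- function(profile, route, dose_mg, n_doses, interval_h, fa, fdp, f,
                    drug, subject, window = 2) {
  ct <- cmax_tmax(profile)
  ai <- auc_infinity(profile, window = window)
  kel <- drug$clearance / (drug$vc_per_kg * subject$body_mass)
  tibble(route = route, dose_mg = dose_mg, n_doses = n_doses,
         interval_h = interval_h,
         fa_pct = 100 * fa, fdp_pct = 100 * fdp, f_pct = 100 * f,
         cmax = ct$cmax, tmax = ct$tmax,
         auc_0_t = ai$auc_0_t, auc_0_inf = ai$auc_0_inf,
         lambda_z = ai$lambda_z,
         accumulation_index = if (n_doses > 1L)
           accumulation_index(kel, interval_h) else NA_real_)
}

#' @rdname summarize_regimen
#' @export
summarize_regimen.acat_simulation <- function(x, ...) {
  nd <- length(x$dose_times)
  interval <- if (nd > 1L) diff(x$dose_times)[1] else NA_real_
  nca_row(pk_profile(x), "oral_tablet_ir", x$dose_amounts[1], nd, interval,
          x$fa, x$fdp, x$f, x$drug, x$subject, ...)
}

#' @rdname summarize_regimen
#' @export
summarize_regimen.pk_profile <- function(x, ...) {
  if (!identical(attr(x, "route"), "iv_infusion"))
    stop_validation("oral profiles are summarised via their simulation object.")
  reg <- attr(x, "regimen")
  nca_row(x, "iv_infusion", reg$dose, reg$n_doses,
          if (reg$n_doses > 1L) reg$interval else NA_real_, 1, 1, 1,
          attr(x, "drug"), attr(x, "subject"), ...)
}
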