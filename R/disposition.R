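#' Closed-form plasma concentration for a constant-rate infusion
#'
#' One-compartment model: during the infusion
#' `C(t) = (R0/CL) (1 - e^{-kt})` with `k = CL/V`; afterwards the
#' end-of-infusion concentration decays mono-exponentially. Serves as the
#' independent oracle for the numerical integrator.
#'
#' @param t Time(s) after the start of the infusion, h (vectorised).
#' @param dose Total infused dose, mg.
#' @param duration Infusion duration, h.
#' @param cl Clearance, L/h.
#' @param v Central volume, L.
#' @return Plasma concentration, mg/L.
#' @export
analytic_infusion_conc <- function(t, dose, duration, cl, v) {
  check_positive(duration, "duration")
  check_positive(cl, "cl")
  check_positive(v, "v")
  k <- cl / v
  r0 <- dose / duration
  c_end <- (r0 / cl) * (1 - exp(-k * duration))
  ifelse(t <= duration,
         (r0 / cl) * (1 - exp(-k * pmax(t, 0))),
         c_end * exp(-k * (t - duration)))
}

new_pk_profile <- function(time_h, conc, route, dosing_times, drug, subject,
                           regimen = NULL) {
  out <- tibble(time_h = time_h, conc = conc)
  attr(out, "route") <- route
  attr(out, "dosing_times") <- dosing_times
  attr(out, "drug") <- drug
  attr(out, "subject") <- subject
  attr(out, "regimen") <- regimen
  class(out) <- c("pk_profile", class(out))
  out
}

#' Simulate an intravenous infusion regimen
#'
#' Integrates `dA/dt = R(t) - (CL/V) A` with a constant infusion rate during
#' each infusion window (event-restart at dose times), RK4 on the output
#' grid. `Cp = A/V` with `V = vc_per_kg * body_mass`.
#'
#' @param drug A [drug_parameters()] object.
#' @param subject A [subject_parameters()] object.
#' @param regimen A [dose_regimen()] with route `"iv_infusion"`.
#' @param control List; `dt_out` output grid step (default 0.01 h), `n_sub`
#'   RK4 substeps per grid step.
#' @return A `pk_profile` tibble (`time_h`, `conc` in mg/L) with route and
#'   dosing-time attributes.
#' @examples
#' reg <- dose_regimen("iv_infusion", dose = 1800, infusion_duration = 0.5)
#' prof <- simulate_iv_infusion(gemcitabine_parameters(),
#'                              subject_parameters(), reg)
#' max(prof$conc)
#' @export
simulate_iv_infusion <- function(drug, subject, regimen, control = list()) {
  validate_regimen(regimen)
  if (regimen$route != "iv_infusion")
    stop_validation("`regimen` must have route 'iv_infusion'.")
  ctl <- modifyList(list(dt_out = 0.01, n_sub = NULL), control)
  dt <- ctl$dt_out
  v <- drug$vc_per_kg * subject$body_mass
  kel <- drug$clearance / v
  n_sub <- ctl$n_sub %||% max(1L, ceiling(dt * kel / 0.2))
  h <- dt / n_sub
  starts <- dosing_times(regimen)
  ends <- starts + regimen$infusion_duration
  steps <- c(starts, ends) / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop_validation("infusion windows must fall on the output grid.")
  rate <- regimen$dose / regimen$infusion_duration

  n_out <- as.integer(round(regimen$sim_duration / dt))
  times <- seq(0, regimen$sim_duration, by = dt)
  amount <- numeric(n_out + 1L)
  a <- 0
  for (j in seq_len(n_out)) {
    t0 <- times[j]
    r <- if (any(t0 >= starts - 1e-12 & t0 < ends - 1e-12)) rate else 0
    for (s in seq_len(n_sub)) {
      k1 <- r - kel * a
      k2 <- r - kel * (a + 0.5 * h * k1)
      k3 <- r - kel * (a + 0.5 * h * k2)
      k4 <- r - kel * (a + h * k3)
      a <- a + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    amount[j + 1L] <- a
  }
  new_pk_profile(times, amount / v, "iv_infusion", starts, drug, subject,
                 regimen)
}

#' Simulate an oral tablet regimen
#'
#' Runs the gut absorption model with every administration added to the
#' running lumen state at its dose time (doses co-mingle in the lumen), the
#' portal flux feeding one-compartment disposition.
#'
#' @param drug,subject,physiology Model inputs; the physiology is typically
#'   first calibrated with [calibrate_asf()].
#' @param regimen A [dose_regimen()] with route `"oral_tablet_ir"`.
#' @param control Solver options, as in [simulate_oral_dose()].
#' @return An `acat_simulation`; extract the plasma profile with
#'   [pk_profile()] and the summary with [glance()].
#' @export
simulate_oral_regimen <- function(drug, subject, physiology, regimen,
                                  control = list()) {
  validate_regimen(regimen)
  if (regimen$route != "oral_tablet_ir")
    stop_validation("`regimen` must have route 'oral_tablet_ir'.")
  td <- dosing_times(regimen)
  acat_simulate(drug, subject, physiology, dose_times = td,
                dose_amounts = rep(regimen$dose, regimen$n_doses),
                dose_volume = regimen$dose_volume,
                sim_duration = regimen$sim_duration, control = control)
}

#' Plasma concentration profile of a simulation
#'
#' @param sim An `acat_simulation` (oral) -- IV simulations already return a
#'   `pk_profile`.
#' @return A `pk_profile` tibble (`time_h`, `conc` mg/L).
#' @export
pk_profile <- function(sim) {
  stopifnot(inherits(sim, "acat_simulation"))
  new_pk_profile(sim$times, sim$conc, "oral_tablet_ir", sim$dose_times,
                 sim$drug, sim$subject)
}
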