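test_that("dissolution follows the Noyes-Whitney driving force", {
  expect_equal(dissolution_rate(0, 0, gem), 0)
  expect_equal(dissolution_rate(100, gem$solubility, gem), 0)
  # unit-conversion oracle: 3 * 0.93e-5 * 3600 / (1200 mg/mL * (25e-4 cm)^2)
  # = 13.392 mL/(mg h); * 100 mg * 5.01 mg/mL = 6709.392 mg/h
  expect_equal(dissolution_rate(100, 0, gem), 6709.392, tolerance = 1e-9)
  # saturation caps the driving force at zero, never negative
  expect_equal(dissolution_rate(100, 10, gem), 0)
})

test_that("precipitation removes supersaturated drug first-order in tau", {
  expect_equal(precipitation_rate(5.01, 5.01, 250, 900), 0)
  expect_equal(precipitation_rate(4, 5.01, 250, 900), 0)
  # (6 - 5.01) mg/mL * 250 mL / 0.25 h = 990 mg/h
  expect_equal(precipitation_rate(6, 5.01, 250, 900), 990)
  expect_equal(precipitation_rate(6, 5.01, 250, 1800),
               precipitation_rate(6, 5.01, 250, 900) / 2)
})

test_that("absorption rate constant is 2 Peff ASF / R in 1/h", {
  comp <- list(radius_cm = 1.75, asf = 1)
  expect_equal(absorption_rate_constant(gem, comp), 2 * 0.59e-4 * 3600 / 1.75)
  expect_equal(absorption_rate_constant(gem, comp) / 3600, 6.7429e-5,
               tolerance = 1e-4)
  expect_equal(absorption_rate_constant(gem, list(radius_cm = 1.75, asf = 0)), 0)
  # linear in Peff
  d2 <- gemcitabine_parameters(peff_jejunal = 2 * gem$peff_jejunal)
  expect_equal(absorption_rate_constant(d2, comp),
               2 * absorption_rate_constant(gem, comp))
})

test_that("the lumen simulation conserves mass and honours limiting cases", {
  sim <- simulate_oral_dose(gem, phys_default, 1000)
  expect_lt(sim$mass_balance_drift, 1e-6 * sim$dose_total)
  expect_true(sim$fa >= sim$fdp && sim$fdp >= sim$f)
  expect_equal(sum(sim$per_compartment_absorbed) / sim$dose_total, sim$fa)

  # no absorbing surface anywhere: everything transits and is excreted
  phys_none <- phys_default
  phys_none$asf <- rep(0, nrow(phys_none))
  s0 <- simulate_oral_dose(gem, phys_none, 1000, sim_duration = 24)
  expect_equal(s0$fa, 0)
  expect_error(regional_absorption_fractions(s0),
               class = "acatpk_validation_error")

  # fast dissolution + huge permeability: absorption is complete
  d_fast <- gemcitabine_parameters(peff_jejunal = 5e-3, particle_radius = 1,
                                   solubility = 100)
  expect_gt(simulate_oral_dose(d_fast, phys_default, 1000)$fa, 0.99)
})

test_that("simulated fa matches the closed-form transit-chain oracle", {
  for (n in c(1L, 3L, 7L)) {
    for (kaT in c(0.1, 1, 10)) {
      ka <- kaT / 3.32
      sim <- simulate_oral_dose(gem_soluble, cat_chain_physiology(n, ka, 3.32),
                                1000, predissolved = TRUE)
      expect_equal(sim$fa, cat_closed_form_fa(ka, 3.32, n),
                   tolerance = 0.005,
                   label = sprintf("fa (n = %d, kaT = %g)", n, kaT))
    }
  }
  # spec anchor: 7 compartments, ka 0.243 1/h, T 3.32 h -> Fa 0.534
  sim <- simulate_oral_dose(gem_soluble, cat_chain_physiology(7L, 0.243, 3.32),
                            1000, predissolved = TRUE)
  expect_equal(sim$fa, 0.534, tolerance = 0.005)
})

test_that("fa responds monotonically to permeability, solubility and transit", {
  fa_at <- function(drug, phys, dose = 1000)
    simulate_oral_dose(drug, phys, dose)$fa
  # permeability
  fa_p <- vapply(c(0.3e-4, 0.59e-4, 1.2e-4), function(p)
    fa_at(gemcitabine_parameters(peff_jejunal = p), phys_default), 0)
  expect_true(all(diff(fa_p) > 0))
  # solubility, stressed with the larger dose
  fa_s <- vapply(c(1, 5.01, 20), function(s)
    fa_at(gemcitabine_parameters(solubility = s), phys_default, dose = 1500), 0)
  expect_true(all(diff(fa_s) >= 0))
  # small-intestinal transit time
  fa_t <- vapply(c(0.7, 1, 1.3), function(scale) {
    phys <- phys_default
    si <- phys$compartment %in% attr(phys, "small_intestine")
    phys$transit_h[si] <- phys$transit_h[si] * scale
    fa_at(gem, phys)
  }, 0)
  expect_true(all(diff(fa_t) > 0))
})

test_that("solubility limitation lowers fa at the higher tablet strength", {
  fa_1000 <- simulate_oral_dose(gem, phys_default, 1000)$fa
  fa_1500 <- simulate_oral_dose(gem, phys_default, 1500)$fa
  expect_lt(fa_1500, fa_1000)
})

test_that("regional fractions normalise the absorption map", {
  sim <- simulate_oral_dose(gem, phys_default, 1000)
  frac <- regional_absorption_fractions(sim)
  expect_equal(sum(frac$fraction), 1, tolerance = 1e-6)
  expect_equal(frac$pct_dose / 100, frac$fraction * sim$fa, tolerance = 1e-9)

  # single absorbing compartment takes everything
  phys_one <- phys_default
  phys_one$asf <- ifelse(phys_one$compartment == "jejunum1", 1, 0)
  f1 <- regional_absorption_fractions(simulate_oral_dose(gem, phys_one, 1000))
  expect_equal(f1$fraction[f1$compartment == "jejunum1"], 1)

  # equal-compartment transit chain: absorption decreases down the intestine
  sim_cat <- simulate_oral_dose(gem_soluble, cat_chain_physiology(7L, 0.3, 3.32),
                                1000, predissolved = TRUE)
  f7 <- regional_absorption_fractions(sim_cat)
  si_frac <- f7$fraction[grepl("^si", f7$compartment)]
  expect_true(all(diff(si_frac) < 0))
})

test_that("lumen trajectories tidy into the long format", {
  sim <- simulate_oral_dose(gem, phys_default, 1000, sim_duration = 2)
  traj <- tidy(sim)
  expect_named(traj, c("time_h", "compartment", "pool", "mass_mg"))
  expect_setequal(unique(traj$pool), c("undissolved", "dissolved", "absorbed"))
  expect_equal(nrow(traj), 201 * 9 * 3)
  # the full dose starts undissolved in the stomach
  start <- dplyr::filter(traj, time_h == 0, pool == "undissolved")
  expect_equal(sum(start$mass_mg), 1000)
})

test_that("calibration hits the target and reports its multipliers", {
  cal <- calibrate_asf(phys_default, gem, subj70, target_fa = 0.68026)
  info <- attr(cal, "calibration")
  expect_equal(info$achieved_fa, 0.68026, tolerance = 2e-3)
  expect_true(info$colon_multiplier > 0 && info$colon_multiplier < 1)
  expect_equal(info$global_multiplier, 1)
  # small-intestine ASFs untouched
  si <- cal$compartment %in% attr(cal, "small_intestine")
  expect_equal(cal$asf[si], phys_default$asf[si])

  # fixed point: asking for the current fa returns multiplier 1
  fa_now <- simulate_oral_dose(gem, phys_default, 1000)$fa
  fix <- calibrate_asf(phys_default, gem, subj70, target_fa = fa_now)
  expect_equal(attr(fix, "calibration")$colon_multiplier, 1)

  # monotone: larger target, larger colon multiplier
  m_lo <- attr(calibrate_asf(phys_default, gem, subj70, target_fa = 0.65),
               "calibration")$colon_multiplier
  m_hi <- attr(calibrate_asf(phys_default, gem, subj70, target_fa = 0.75),
               "calibration")$colon_multiplier
  expect_lt(m_lo, m_hi)

  # unreachable target errors with the attainable range: a near-impermeable
  # drug cannot reach 68% absorption with any admissible scale factor
  d_low <- gemcitabine_parameters(peff_jejunal = 1e-9)
  expect_error(calibrate_asf(phys_default, d_low, subj70, target_fa = 0.68),
               class = "acatpk_calibration_error")
})
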