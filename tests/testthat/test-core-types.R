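test_that("gemcitabine defaults carry the case-study parameter set", {
  expect_equal(gem$molecular_weight, 263.2)
  expect_equal(gem$logp, -1.32)
  expect_equal(gem$solubility, 5.01)
  expect_equal(gem$solubility_ph, 7.92)
  expect_equal(gem$mean_precipitation_time, 900)
  expect_equal(gem$particle_density, 1.2)
  expect_equal(gem$diffusion_coefficient, 0.93e-5)
  expect_equal(gem$blood_plasma_ratio, 1.12)
  expect_equal(gem$peff_jejunal, 0.59e-4)
  expect_equal(gem$fup, 0.846)
  expect_equal(gem$vc_per_kg, 1.45)
  expect_equal(gem$clearance, 120)
})

test_that("drug parameter validation rejects out-of-range values", {
  expect_error(gemcitabine_parameters(fup = 0), class = "acatpk_validation_error")
  expect_error(gemcitabine_parameters(fup = 1.2), class = "acatpk_validation_error")
  expect_error(gemcitabine_parameters(solubility = -1),
               class = "acatpk_validation_error")
  expect_error(gemcitabine_parameters(solubility_ph = 15),
               class = "acatpk_validation_error")
  expect_error(subject_parameters(body_mass = 0),
               class = "acatpk_validation_error")
  # pass-through of a modified but valid value
  expect_equal(gemcitabine_parameters(solubility = 50.1)$solubility, 50.1)
})

test_that("packaged drug config loads and round-trips", {
  cfg <- system.file("extdata", "gemcitabine_drug.cfg", package = "acatpk")
  drug <- load_drug_parameters(cfg)
  expect_s3_class(drug, "drug_parameters")
  expect_equal(drug$clearance, 120)
  expect_equal(drug$peff_jejunal, 0.59e-4)
  expect_identical(unclass(drug), unclass(gem))

  # serialize -> reload -> identical
  tmp <- withr::local_tempfile(fileext = ".cfg")
  write_config(drug, tmp)
  again <- load_drug_parameters(tmp)
  expect_identical(again$name, drug$name)
  for (f in setdiff(names(drug), "name"))
    expect_equal(again[[f]], drug[[f]], tolerance = 1e-12)

  # a config missing a field errors naming it
  short <- withr::local_tempfile(fileext = ".cfg")
  writeLines("name = \"x\"\nclearance = 10", short)
  expect_error(load_drug_parameters(short), "molecular_weight")
})

test_that("regimen invariants catch mis-specified schedules", {
  expect_s3_class(dose_regimen("iv_infusion", dose = 1800,
                               infusion_duration = 0.5), "dose_regimen")
  oral <- dose_regimen("oral_tablet_ir", dose = 1000, interval = 8,
                       n_doses = 3)
  expect_equal(oral$dose_volume, 250)
  # third dose outside the 24 h horizon
  expect_error(dose_regimen("oral_tablet_ir", dose = 1000, interval = 24,
                            n_doses = 3), class = "acatpk_validation_error")
  # route/field mismatches
  expect_error(dose_regimen("oral_tablet_ir", dose = 1000,
                            infusion_duration = 0.5),
               class = "acatpk_validation_error")
  expect_error(dose_regimen("iv_infusion", dose = 1800,
                            infusion_duration = 0.5, dose_volume = 250),
               class = "acatpk_validation_error")
  expect_error(dose_regimen("iv_infusion", dose = 1800),
               class = "acatpk_validation_error")
})

test_that("regimen configs round-trip through key = value files", {
  reg <- dose_regimen("oral_tablet_ir", dose = 1500, interval = 12,
                      n_doses = 2, sim_duration = 24)
  tmp <- withr::local_tempfile(fileext = ".cfg")
  write_config(reg, tmp)
  again <- load_regimen(tmp)
  expect_equal(unclass(again), unclass(reg))
  pkg_reg <- load_regimen(system.file("extdata", "regimen_iv_1800.cfg",
                                      package = "acatpk"))
  expect_equal(pkg_reg$dose, 1800)
  expect_equal(pkg_reg$infusion_duration, 0.5)
})

test_that("default physiology has the documented fasted-state structure", {
  expect_equal(nrow(phys_default), 9L)
  expect_identical(phys_default$compartment[1], "stomach")
  expect_identical(phys_default$compartment[9], "asc_colon")
  expect_false(anyDuplicated(phys_default$compartment) > 0)
  expect_equal(phys_default$asf[1], 0)  # stomach never absorbs
  # small-intestinal transit sums to ~3.3 h
  expect_equal(small_intestine_transit(phys_default), 3.3, tolerance = 0.1 / 3.3)
  # deterministic
  expect_identical(default_human_physiology(), default_human_physiology())
  expect_error(default_human_physiology(body_mass = -1),
               class = "acatpk_validation_error")
})

test_that("JSON export writes a parseable snapshot", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_config_json(gem, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$clearance, 120)
  expect_equal(back$peff_jejunal, 0.59e-4)
})
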