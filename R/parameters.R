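#' Drug parameter set
#'
#' Bundles the physicochemical and pharmacokinetic inputs the absorption and
#' disposition models need. Units follow common simulator conventions and are
#' fixed at construction time: all conversions happen downstream.
#'
#' @param name Drug name.
#' @param molecular_weight g/mol.
#' @param logp Octanol/water log partition coefficient (neutral species).
#' @param solubility Reference aqueous solubility, mg/mL.
#' @param solubility_ph pH at which `solubility` applies (0--14).
#' @param mean_precipitation_time Mean precipitation time, seconds; first-order
#'   time constant with which supersaturated dissolved drug returns to the
#'   solid (re-dissolvable) pool.
#' @param particle_density Solid drug particle density, g/mL.
#' @param particle_radius Particle radius, micrometres.
#' @param diffusion_coefficient Aqueous diffusion coefficient, cm^2/s.
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio (carried as
#'   information; the linear disposition model does not use it).
#' @param peff_jejunal Human effective jejunal permeability, cm/s.
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param vc_per_kg Central volume of distribution, L/kg.
#' @param clearance Systemic clearance, L/h.
#'
#' @return A `drug_parameters` object (named list).
#' @seealso [gemcitabine_parameters()] for the packaged gemcitabine set.
#' @export
drug_parameters <- function(name, molecular_weight, logp, solubility,
                            solubility_ph, mean_precipitation_time,
                            particle_density, particle_radius,
                            diffusion_coefficient, blood_plasma_ratio,
                            peff_jejunal, fup, vc_per_kg, clearance) {
  x <- list(
    name = as.character(name)[1],
    molecular_weight = molecular_weight, logp = logp,
    solubility = solubility, solubility_ph = solubility_ph,
    mean_precipitation_time = mean_precipitation_time,
    particle_density = particle_density, particle_radius = particle_radius,
    diffusion_coefficient = diffusion_coefficient,
    blood_plasma_ratio = blood_plasma_ratio, peff_jejunal = peff_jejunal,
    fup = fup, vc_per_kg = vc_per_kg, clearance = clearance
  )
  class(x) <- "drug_parameters"
  validate_drug_parameters(x)
}

validate_drug_parameters <- function(x) {
  for (f in c("molecular_weight", "solubility", "mean_precipitation_time",
              "particle_density", "particle_radius", "diffusion_coefficient",
              "blood_plasma_ratio", "peff_jejunal", "vc_per_kg", "clearance"))
    check_positive(x[[f]], f)
  if (!is.numeric(x$logp) || length(x$logp) != 1L || !is.finite(x$logp))
    stop_validation("`logp` must be a single finite number.")
  check_fraction(x$fup, "fup")
  if (x$solubility_ph < 0 || x$solubility_ph > 14)
    stop_validation("`solubility_ph` must lie in [0, 14].")
  x
}

#' Gemcitabine parameter set
#'
#' The packaged gemcitabine case-study parameters: solubility 5.01 mg/mL at pH
#' 7.92, effective jejunal permeability 0.59e-4 cm/s, Vc 1.45 L/kg and
#' systemic clearance 120 L/h. The diffusion coefficient is 0.93e-5 cm^2/s;
#' the particle radius (25 um) is a common simulator default, configurable via
#' `...`.
#'
#' @param ... Named fields overriding the defaults, passed to
#'   [drug_parameters()].
#' @return A `drug_parameters` object.
#' @examples
#' gemcitabine_parameters()$clearance
#' @export
gemcitabine_parameters <- function(...) {
  defaults <- list(
    name = "gemcitabine", molecular_weight = 263.2, logp = -1.32,
    solubility = 5.01, solubility_ph = 7.92,
    mean_precipitation_time = 900, particle_density = 1.2,
    particle_radius = 25, diffusion_coefficient = 0.93e-5,
    blood_plasma_ratio = 1.12, peff_jejunal = 0.59e-4, fup = 0.846,
    vc_per_kg = 1.45, clearance = 120
  )
  do.call(drug_parameters, modifyList(defaults, list(...)))
}

#' Subject parameters
#'
#' @param body_mass Body mass in kg (default 70; chosen so that a central
#'   volume of 1.45 L/kg gives 101.5 L and an elimination half-life of
#'   ln(2) * 101.5 / 120 = 0.59 h for the gemcitabine defaults).
#' @return A `subject_parameters` object.
#' @export
subject_parameters <- function(body_mass = 70) {
  check_positive(body_mass, "body_mass")
  structure(list(body_mass = body_mass), class = "subject_parameters")
}

#' Dosing regimen
#'
#' @param route `"iv_infusion"` or `"oral_tablet_ir"` (immediate-release
#'   tablet).
#' @param dose Dose per administration, mg.
#' @param interval Dosing interval, h (required when `n_doses > 1`).
#' @param n_doses Number of administrations within the simulation.
#' @param infusion_duration Infusion length in h (IV only).
#' @param dose_volume Fluid volume taken with each oral dose, mL (default
#'   250).
#' @param sim_duration Simulation horizon, h (default 24).
#' @return A validated `dose_regimen` object.
#' @export
dose_regimen <- function(route = c("iv_infusion", "oral_tablet_ir"), dose,
                         interval = NA_real_, n_doses = 1L,
                         infusion_duration = NA_real_, dose_volume = NA_real_,
                         sim_duration = 24) {
  route <- match.arg(route)
  if (route == "oral_tablet_ir" && is.na(dose_volume)) dose_volume <- 250
  x <- structure(
    list(route = route, dose = dose, interval = interval,
         n_doses = as.integer(n_doses), infusion_duration = infusion_duration,
         dose_volume = dose_volume, sim_duration = sim_duration),
    class = "dose_regimen"
  )
  validate_regimen(x)
}

#' Validate a dosing regimen
#'
#' Checks the structural invariants: positive dose, all administrations inside
#' the simulation horizon, an infusion duration for IV regimens only, and a
#' dose volume for oral regimens only.
#'
#' @param regimen A `dose_regimen` object.
#' @return The regimen, unchanged, if valid; otherwise an error.
#' @export
validate_regimen <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  check_positive(regimen$dose, "dose")
  check_positive(regimen$sim_duration, "sim_duration")
  if (regimen$n_doses < 1L) stop_validation("`n_doses` must be >= 1.")
  if (regimen$n_doses > 1L) {
    check_positive(regimen$interval, "interval")
    if ((regimen$n_doses - 1L) * regimen$interval >= regimen$sim_duration)
      stop_validation(
        "the last administration falls outside the simulation horizon.")
  }
  if (regimen$route == "iv_infusion") {
    check_positive(regimen$infusion_duration, "infusion_duration")
    if (!is.na(regimen$dose_volume))
      stop_validation("IV regimens must not set `dose_volume`.")
  } else {
    check_positive(regimen$dose_volume, "dose_volume")
    if (!is.na(regimen$infusion_duration))
      stop_validation("oral regimens must not set `infusion_duration`.")
  }
  regimen
}

dosing_times <- function(regimen) {
  if (regimen$n_doses == 1L) 0 else (seq_len(regimen$n_doses) - 1) * regimen$interval
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>", x$name, "\n")
  flds <- setdiff(names(x), "name")
  cat(paste0("  ", flds, ": ", vapply(x[flds], format, "")), sep = "\n")
  invisible(x)
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat("<dose_regimen>", x$route, sprintf("%g mg x %d", x$dose, x$n_doses),
      if (x$n_doses > 1L) sprintf("q%gh", x$interval) else "",
      sprintf("over %g h\n", x$sim_duration))
  invisible(x)
}

# configuration files --------------------------------------------------------

#' Read a key = value configuration file
#'
#' The configuration format is a TOML-like subset: one `key = value` pair per
#' line, `#` comments, numbers parsed as numerics, everything else as strings
#' (surrounding quotes stripped). Section headers (`[...]`) are ignored.
#'
#' @param path File path.
#' @return Named list of values.
#' @keywords internal
parse_kv_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("config `%s` not found.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_validation(sprintf("malformed config line: `%s`", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

required_fields <- function(cfg, fields, what) {
  missing <- setdiff(fields, names(cfg))
  if (length(missing))
    stop_validation(sprintf("%s config is missing field(s): %s", what,
                            paste(missing, collapse = ", ")))
  invisible(cfg)
}

#' Load drug parameters from a configuration file
#'
#' @param path Path to a `key = value` drug configuration (see
#'   `system.file("extdata", "gemcitabine_drug.cfg", package = "acatpk")` for
#'   the schema).
#' @return A validated `drug_parameters` object.
#' @export
load_drug_parameters <- function(path) {
  cfg <- parse_kv_config(path)
  flds <- c("name", "molecular_weight", "logp", "solubility", "solubility_ph",
            "mean_precipitation_time", "particle_density", "particle_radius",
            "diffusion_coefficient", "blood_plasma_ratio", "peff_jejunal",
            "fup", "vc_per_kg", "clearance")
  required_fields(cfg, flds, "drug")
  do.call(drug_parameters, cfg[flds])
}

#' Load a dosing regimen from a configuration file
#'
#' @param path Path to a `key = value` regimen configuration.
#' @return A validated `dose_regimen` object.
#' @export
load_regimen <- function(path) {
  cfg <- parse_kv_config(path)
  required_fields(cfg, c("route", "dose"), "regimen")
  do.call(dose_regimen, cfg[intersect(names(cfg), names(formals(dose_regimen)))])
}

#' Load subject parameters from a configuration file
#' @param path Path to a `key = value` subject configuration.
#' @return A `subject_parameters` object.
#' @export
load_subject_parameters <- function(path) {
  cfg <- parse_kv_config(path)
  required_fields(cfg, "body_mass", "subject")
  subject_parameters(body_mass = cfg$body_mass)
}

#' Export a validated object as JSON
#'
#' @param x A `drug_parameters`, `subject_parameters`, `dose_regimen` or
#'   `gi_physiology` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Serialise a parameter object to a key = value configuration file
#'
#' Round-trips with [load_drug_parameters()] / [load_regimen()] /
#' [load_subject_parameters()].
#'
#' @param x A `drug_parameters`, `dose_regimen` or `subject_parameters`
#'   object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  vals <- unclass(x)
  vals <- vals[!vapply(vals, function(v) length(v) == 1L && is.na(v), TRUE)]
  fmt <- vapply(vals, function(v) {
    if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 17)
  }, "")
  writeLines(paste(names(vals), "=", fmt), path)
  invisible(path)
}
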