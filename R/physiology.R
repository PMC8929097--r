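#' Default fasted human gastrointestinal physiology
#'
#' A nine-compartment fasted-state gut: stomach, duodenum, two jejunal and
#' three ileal segments, caecum and ascending colon. Volumes, radii and mean
#' transit times are defaults adapted from the published compartmental
#' absorption-and-transit literature; small-intestinal transit sums to about
#' 3.3 h. The stomach has absorption scale factor (ASF) 0 (non-absorbing);
#' every other compartment starts at ASF 1 until calibrated (see
#' [calibrate_asf()]).
#'
#' @param body_mass Body mass in kg. The default table is referenced to a
#'   70 kg adult; physiology scaling with mass is not modelled, but the value
#'   must be positive and is carried as an attribute.
#' @return A `gi_physiology` tibble with columns `compartment`, `volume_ml`,
#'   `radius_cm`, `transit_h`, `ph` and `asf`, ordered stomach first, colon
#'   last. Attributes: `small_intestine` (compartment names used by
#'   closed-form transit oracles), `body_mass`.
#' @examples
#' default_human_physiology()
#' @export
default_human_physiology <- function(body_mass = 70) {
  check_positive(body_mass, "body_mass")
  phys <- tibble(
    compartment = c("stomach", "duodenum", "jejunum1", "jejunum2", "ileum1",
                    "ileum2", "ileum3", "caecum", "asc_colon"),
    volume_ml = c(47, 42, 154, 122, 94, 71, 49, 47, 50),
    radius_cm = c(9.67, 1.60, 1.53, 1.45, 1.33, 1.21, 1.08, 3.39, 2.41),
    transit_h = c(0.25, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 4.50, 13.50),
    ph = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
    asf = c(0, 1, 1, 1, 1, 1, 1, 1, 1)
  )
  new_gi_physiology(phys,
                    small_intestine = c("duodenum", "jejunum1", "jejunum2",
                                        "ileum1", "ileum2", "ileum3"),
                    body_mass = body_mass)
}

new_gi_physiology <- function(tbl, small_intestine, body_mass = 70,
                              calibration = NULL) {
  tbl <- as_tibble(tbl)
  attr(tbl, "small_intestine") <- small_intestine
  attr(tbl, "body_mass") <- body_mass
  attr(tbl, "calibration") <- calibration
  class(tbl) <- c("gi_physiology", class(tbl))
  validate_physiology(tbl)
}

#' Validate a GI physiology table
#'
#' @param physiology A `gi_physiology` tibble.
#' @return The physiology, unchanged, if valid.
#' @export
validate_physiology <- function(physiology) {
  req <- c("compartment", "volume_ml", "radius_cm", "transit_h", "asf")
  missing <- setdiff(req, names(physiology))
  if (length(missing))
    stop_validation(paste("physiology lacks column(s):",
                          paste(missing, collapse = ", ")))
  if (nrow(physiology) < 3L)
    stop_validation("a physiology needs at least 3 compartments.")
  if (anyDuplicated(physiology$compartment))
    stop_validation("compartment names must be unique.")
  for (col in c("volume_ml", "radius_cm", "transit_h"))
    if (any(physiology[[col]] <= 0))
      stop_validation(sprintf("`%s` must be > 0 in every compartment.", col))
  check_nonnegative(physiology$asf, "asf")
  physiology
}

#' Small-intestinal transit time of a physiology
#'
#' @param physiology A `gi_physiology` tibble.
#' @return Total mean transit time (h) over the compartments flagged as small
#'   intestine.
#' @export
small_intestine_transit <- function(physiology) {
  si <- attr(physiology, "small_intestine")
  sum(physiology$transit_h[physiology$compartment %in% si])
}
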