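#' Plot a plasma concentration-time profile
#'
#' @param object A `pk_profile`.
#' @param ... Unused.
#' @return A ggplot: concentration against time with dashed rules at dosing
#'   events.
#' @export
autoplot.pk_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$conc)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (mg/L)") +
    ggplot2::theme_minimal()
  dt <- attr(object, "dosing_times")
  if (length(dt) > 1L)
    p <- p + ggplot2::geom_vline(xintercept = dt, linetype = "dashed",
                                 colour = "grey60")
  p
}

#' Plot a gut-model simulation
#'
#' @param object An `acat_simulation`.
#' @param type `"profile"` (plasma curve), `"lumen"` (per-compartment mass
#'   trajectories by pool) or `"regional"` (share of absorbed dose per
#'   compartment).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acat_simulation <- function(object,
                                     type = c("profile", "lumen", "regional"),
                                     ...) {
  type <- match.arg(type)
  if (type == "profile") return(autoplot(pk_profile(object)))
  if (type == "lumen") {
    traj <- tidy(object) |>
      dplyr::mutate(compartment = factor(.data$compartment,
                                         levels = object$compartments))
    return(
      ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_h, y = .data$mass_mg,
                                         colour = .data$compartment)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~pool, scales = "free_y") +
        ggplot2::labs(x = "Time (h)", y = "Mass (mg)") +
        ggplot2::theme_minimal()
    )
  }
  frac <- regional_absorption_fractions(object) |>
    dplyr::mutate(compartment = factor(.data$compartment,
                                       levels = object$compartments))
  ggplot2::ggplot(frac, ggplot2::aes(x = .data$compartment,
                                     y = .data$pct_dose)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "Absorbed (% of dose)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a transwell assay with its fitted transport line
#'
#' @param object A tibble from [generate_caco2_assay()] (or the same
#'   columns).
#' @param protocol The matching [assay_protocol()].
#' @param ... Unused.
#' @return A ggplot of cumulative transported amount per replicate with the
#'   pooled OLS fit.
#' @export
plot_assay <- function(object, protocol = assay_protocol(), ...) {
  cum <- object |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::mutate(cumulative = cumulative_transported(
      .data$receiver_conc, protocol$receiver_volume, protocol$sample_volume)) |>
    dplyr::ungroup()
  ggplot2::ggplot(cum, ggplot2::aes(x = .data$time_min, y = .data$cumulative,
                                    group = .data$replicate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(ggplot2::aes(group = NULL), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "#b2182b") +
    ggplot2::labs(x = "Time (min)", y = "Cumulative transported (umol)") +
    ggplot2::theme_minimal()
}
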