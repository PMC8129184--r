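#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a material-card set as a stiffness ladder
#'
#' @param object A `material_card_set`.
#' @param ... Unused.
#' @return A ggplot: per-part Ogden `mu` against relative stiffness gamma.
#' @export
autoplot.material_card_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = gamma, y = mu_kpa)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "relative stiffness γ",
                  y = "Ogden μ (kPa)",
                  title = sprintf("Heterogeneous cards: μ₀,med = %.3g kPa, α = %.3g",
                                  object$mu0_med, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a golden-section search trace
#'
#' @param object A `golden_search` object.
#' @param ... Unused.
#' @return A ggplot of all objective evaluations with the bracket shrink.
#' @export
autoplot.golden_search <- function(object, ...) {
  led <- dplyr::filter(object$ledger, !reused)
  span <- max(diff(range(led$value)), 1e-6)
  tr <- dplyr::mutate(object$trace,
                      y = min(led$value) - 0.04 * span * iteration)
  ggplot2::ggplot(led, ggplot2::aes(x = param, y = value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(data = tr,
                          ggplot2::aes(x = a, xend = b, y = y, yend = y),
                          inherit.aes = FALSE, colour = "steelblue",
                          linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = object$argmax, linetype = 2) +
    ggplot2::labs(x = "parameter", y = "objective",
                  title = sprintf("Golden-section search: argmax %.4g after %d iterations",
                                  object$argmax, object$iterations)) +
    ggplot2::theme_minimal()
}

#' Plot per-receiver composite ratings of a case
#'
#' @param object A `case_rating` from [weighted_overall()].
#' @param ... Unused.
#' @return A ggplot of per-receiver cCORA (point size = receiver weight).
#' @export
autoplot.case_rating <- function(object, ...) {
  d <- dplyr::mutate(object$ratings, weight = object$weights)
  if (!"receiver" %in% names(d)) d$receiver <- as.character(seq_len(nrow(d)))
  ggplot2::ggplot(d, ggplot2::aes(x = receiver, y = ccora, size = weight)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$wccora, linetype = 2, colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "cCORA", title = sprintf("wcCORA = %.3f", object$wccora)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the verification matrix of a calibration report
#'
#' @param object A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot of wcCORA per subject and case.
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(object$verification,
                  ggplot2::aes(x = case_id, y = wccora, colour = subject,
                               group = subject)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "wcCORA",
                  title = sprintf("Verification: mean wcCORA %.3f ± %.3f",
                                  object$summary$mean_wccora, object$summary$sd_wccora)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot single-element loading curves
#'
#' @param curves A tibble from [single_element_curves()] (rows from several
#'   calls may be bound together).
#' @return A ggplot of stress against strain, coloured by rate, faceted by
#'   mode when several modes are present.
#' @export
plot_single_element_curves <- function(curves) {
  stopifnot(all(c("strain", "stress_kpa", "mode", "rate_per_s") %in% names(curves)))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = strain, y = stress_kpa,
                                    colour = factor(rate_per_s))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "engineering strain", y = "nominal stress (kPa)",
                  colour = "rate (1/s)") +
    ggplot2::theme_minimal()
  if (length(unique(curves$mode)) > 1) p <- p + ggplot2::facet_wrap(~mode)
  p
}

#' Plot tan(delta) of a relaxation spectrum over frequency
#'
#' @param prony A [prony_series()].
#' @param freq Frequencies, Hz (default 30 log-spaced points in 0.1-1000 Hz).
#' @param data Optional data frame with `freq_hz`, `tan_delta` overlaid as
#'   points.
#' @return A ggplot.
#' @export
plot_tan_delta <- function(prony, freq = 10^seq(-1, 3, length.out = 60),
                           data = NULL) {
  d <- tibble::tibble(freq_hz = freq, tan_delta = tan_delta(freq, prony))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = freq_hz, y = tan_delta)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "tan(δ)") +
    ggplot2::theme_minimal()
  if (!is.null(data))
    p <- p + ggplot2::geom_point(data = data, colour = "firebrick", alpha = 0.6)
  p
}
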