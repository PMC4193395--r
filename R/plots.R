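#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PSD matrix as a spectrogram heat map
#' @param object A `bci_psd`.
#' @param trans Transformation of power for display, `"db"` (default) or
#'   `"linear"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bci_psd <- function(object, trans = c("db", "linear"), ...) {
  trans <- match.arg(trans)
  df <- as_tibble(object)
  if (trans == "db") {
    floor_db <- max(df$psd) * 1e-8
    df$psd <- 10 * log10(pmax(df$psd, floor_db))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$freq_hz,
                                   fill = .data$psd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (trans == "db") "PSD (dB)" else "PSD") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a ratio trace with an optional threshold line
#' @param object A `ratio_trace`.
#' @param threshold Optional horizontal threshold in dB.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ratio_trace <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[is.finite(df$ratio_db), ],
                       ggplot2::aes(.data$time_ms / 1000, .data$ratio_db)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "Time (s)",
      y = sprintf("10 log10(beta^%d / alpha) (dB)", object$exponent)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' Plot a coherogram heat map
#' @param object A `coherogram`.
#' @param max_freq Upper frequency limit of the display (default 45 Hz).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coherogram <- function(object, max_freq = 45, ...) {
  df <- dplyr::filter(as_tibble(object), .data$freq_hz <= max_freq)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$freq_hz,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Coherence", limits = c(0, 1)) +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot quality parameter against detection threshold
#'
#' Mean curve with an SD ribbon and the 95% CI band, one facet per ratio
#' exponent.
#'
#' @param object A `qp_curve` from [qp_threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qp_curve <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    ratio = ifelse(.data$exponent == 1, "beta/alpha", "beta^2/alpha"))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$qp_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$qp_mean - .data$qp_sd),
                   ymax = pmin(100, .data$qp_mean + .data$qp_sd)),
      fill = "grey80") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ratio) +
    ggplot2::labs(x = "Threshold (SD units from the mean)", y = "QP (%)") +
    ggplot2::theme_minimal()
}

#' Plot detected movement windows over a signal
#' @param object A `movement_windows` tibble.
#' @param ts Optional [bci_ts()] drawn underneath.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.movement_windows <- function(object, ts = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(ts)) {
    p <- p + ggplot2::geom_line(
      data = as_tibble(ts),
      ggplot2::aes(.data$time_ms / 1000, .data$value), color = "grey40")
  }
  p +
    ggplot2::geom_rect(
      data = tibble::as_tibble(object),
      ggplot2::aes(xmin = .data$extended_start / 1000,
                   xmax = .data$end / 1000, ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.25) +
    ggplot2::geom_vline(
      data = tibble::as_tibble(object),
      ggplot2::aes(xintercept = .data$start / 1000),
      linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
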