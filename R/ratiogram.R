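#' Band-power ratiogram of an EEG PSD
#'
#' The spectrogram-like trace driving ERD/ERS detection: per frame,
#' \deqn{ratio(t) = 10 \log_{10} \frac{(\sum_{f \in \beta} P)^n}
#'                                    {\sum_{f' \in \alpha} P}}
#' with `n = 1` (simple ratio) or `n = 2` (squared ratio).  A burst of
#' beta--gamma power, or an alpha desynchronization, both raise the trace.
#' Band limits are inclusive on the PSD's frequency grid.
#'
#' @param psd A `bci_psd` over a grid containing both bands.
#' @param beta_band Length-2 Hz interval of the beta--gamma numerator
#'   (default `c(13, 40)`).
#' @param alpha_band Length-2 Hz interval of the alpha denominator
#'   (default `c(8, 12)`).
#' @param exponent 1 or 2.
#' @param channel Optional EEG channel label carried along for reporting.
#' @return A list of class `ratio_trace`: `values` (dB per frame, `Inf`
#'   where the alpha band has zero power -- those frames are listed in
#'   `flagged`), `frame_times` (ms), `beta_band`, `alpha_band`, `exponent`,
#'   `channel`.
#' @examples
#' ts <- bci_ts(sin(2 * pi * 10 * (0:2999) / 1000), fs = 1000)
#' rt <- ratiogram(spectrogram(ts), beta_band = c(26, 33),
#'                 alpha_band = c(8, 10))
#' head(rt$values)
#' @export
ratiogram <- function(psd, beta_band = c(13, 40), alpha_band = c(8, 12),
                      exponent = 1, channel = "") {
  stopifnot(inherits(psd, "bci_psd"), exponent %in% c(1, 2))
  beta <- .band_power(psd, beta_band)
  alpha <- .band_power(psd, alpha_band)
  vals <- ifelse(alpha > 0, 10 * log10(beta^exponent / alpha), Inf)
  structure(
    list(values = vals, frame_times = psd$frame_times,
         beta_band = beta_band, alpha_band = alpha_band,
         exponent = exponent, channel = channel,
         flagged = which(alpha <= 0)),
    class = "ratio_trace"
  )
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf(
    "<ratio_trace> %s beta %g-%g Hz ^%d / alpha %g-%g Hz, %d frames%s\n",
    if (nzchar(x$channel)) x$channel else "", x$beta_band[1], x$beta_band[2],
    x$exponent, x$alpha_band[1], x$alpha_band[2], length(x$values),
    if (length(x$flagged)) sprintf(" (%d flagged)", length(x$flagged)) else ""))
  invisible(x)
}

#' Convert a ratio trace to a tibble
#' @param x A `ratio_trace`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `ratio_db`.
#' @exportS3Method tibble::as_tibble
as_tibble.ratio_trace <- function(x, ...) {
  tibble::tibble(time_ms = x$frame_times, ratio_db = x$values)
}

#' Detect supra-threshold peaks of a ratio trace
#'
#' Events are the local maxima of the trace that exceed `threshold`;
#' a run of consecutive supra-threshold frames collapses to its single
#' maximal frame.  A run already in progress at the very first frame is
#' not counted: a peak requires an upward crossing of the threshold.
#' Flagged (infinite) frames are excluded.
#'
#' @param trace A `ratio_trace` (or any list with `values` and
#'   `frame_times`).
#' @param threshold Threshold in dB.  Typical operating points sit near
#'   `ratio_threshold(trace)` (mean + c * SD).
#' @return Numeric vector of event times in ms.
#' @export
detect_ratio_events <- function(trace, threshold) {
  v <- trace$values
  v[!is.finite(v)] <- -Inf
  above <- v > threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  starts <- starts[r$values]
  ends <- ends[r$values]
  keep <- starts > 1   # peak requires an upward crossing
  if (!any(keep)) return(numeric(0))
  apex <- mapply(function(s, e) s - 1 + which.max(v[s:e]),
                 starts[keep], ends[keep])
  trace$frame_times[apex]
}

#' Data-driven ratio threshold (mean + c * SD)
#'
#' @param trace A `ratio_trace`.
#' @param c_sd SD multiplier (default 1).
#' @return Threshold in dB.
#' @export
ratio_threshold <- function(trace, c_sd = 1) {
  v <- trace$values[is.finite(trace$values)]
  mean(v) + c_sd * stats::sd(v)
}

#' Catalog of alpha and beta--gamma sub-bands
#'
#' The default sub-band inventory scanned when searching for the most
#' reactive band pair: the full alpha band with its halves, and a nested
#' split of the 13--40 Hz beta--gamma range.
#'
#' @return A list with elements `alpha` and `beta`, each a list of
#'   length-2 Hz intervals.
#' @export
band_catalog <- function() {
  list(
    alpha = list(c(8, 12), c(8, 10), c(10, 12)),
    beta = list(c(13, 40), c(13, 26), c(26, 40), c(13, 20), c(20, 26),
                c(26, 33), c(33, 40), c(13, 16), c(16, 20), c(20, 23),
                c(23, 26), c(26, 30), c(30, 33))
  )
}

#' Scan all band pairs for the best quality parameter
#'
#' Computes a ratiogram for every (beta sub-band, alpha sub-band, exponent)
#' combination in the catalog, detects events at a mean + `c_sd` * SD
#' threshold, and scores each against the movement list.  Per-pair failures
#' (e.g. all-flagged traces) are returned as rows with `NA` statistics and
#' the condition message in `note`, rather than aborting the scan.
#'
#' @param psd A `bci_psd` of one EEG channel.
#' @param movements A `movement_windows` tibble.
#' @param catalog Band catalog as from [band_catalog()].
#' @param exponents Integer vector within `c(1, 2)`.
#' @param c_sd SD multiplier of the threshold rule.
#' @param ... Passed to [eeg_quality_parameter()].
#' @return A tibble with one row per (beta, alpha, exponent): columns
#'   `beta_lo`, `beta_hi`, `alpha_lo`, `alpha_hi`, `exponent`, `threshold`,
#'   `p`, `d`, `qp`, `n_events`, `note`, sorted by decreasing `qp`.
#' @export
band_pair_scan <- function(psd, movements, catalog = band_catalog(),
                           exponents = c(1, 2), c_sd = 1, ...) {
  grid <- tidyr::expand_grid(
    beta = catalog$beta, alpha = catalog$alpha, exponent = exponents
  )
  rows <- purrr::pmap(grid, function(beta, alpha, exponent) {
    res <- tryCatch({
      rt <- ratiogram(psd, beta_band = beta, alpha_band = alpha,
                      exponent = exponent)
      thr <- ratio_threshold(rt, c_sd)
      ev <- detect_ratio_events(rt, thr)
      res <- eeg_quality_parameter(ev, movements, ...)
      tibble::tibble(threshold = thr, p = res$p, d = res$d, qp = res$qp,
                     n_events = res$n_events, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(threshold = NA_real_, p = NA_real_, d = NA_real_,
                     qp = NA_real_, n_events = NA_integer_,
                     note = conditionMessage(e))
    })
    dplyr::bind_cols(
      tibble::tibble(beta_lo = beta[1], beta_hi = beta[2],
                     alpha_lo = alpha[1], alpha_hi = alpha[2],
                     exponent = exponent),
      res
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$qp))
}
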