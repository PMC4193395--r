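#' Gyroscope tremor spectrogram
#'
#' Goertzel spectrogram of one (1 kHz, upsampled) gyroscope axis over
#' 1--20 Hz with the standard window (256 samples, overlap 250) and the
#' one-sided PSD normalization.
#'
#' @param gyro_axis A [bci_ts()] gyroscope axis at 1000 Hz.
#' @param freqs Frequency grid in Hz (default `1:20`).
#' @return A `bci_psd`.
#' @export
kinematic_spectrogram <- function(gyro_axis, freqs = 1:20) {
  spectrogram(gyro_axis, freqs = freqs, window_len = 256, overlap = 250)
}

#' Early-detection features of the tremor spectrogram
#'
#' Two per-frame features capture the pre-movement reorganization of rest
#' tremor: the ratio of high-band (7--20 Hz) to low-band (1--7 Hz) power,
#' and the maximum PSD inside the low band.  Each feature gets its own
#' threshold, the standard deviation of that feature's trace.  (The low
#' band starts at 1 Hz because the spectrogram grid does.)
#'
#' @param psd A `bci_psd` over 1--20 Hz from [kinematic_spectrogram()].
#' @param split_hz Boundary between the low and high band (default 7;
#'   the boundary bin belongs to both inclusive bands).
#' @return A list of class `kinematic_features`: `ratio`, `maxpsd`
#'   (per-frame vectors; `ratio` is `Inf` on frames with zero low-band
#'   power, listed in `flagged`), `T_ratio`, `T_maxpsd` (SD thresholds),
#'   `frame_times` (ms), `axis`.
#' @export
kinematic_features <- function(psd, split_hz = 7) {
  stopifnot(inherits(psd, "bci_psd"))
  low <- psd$freqs <= split_hz
  high <- psd$freqs >= split_hz
  lowp <- colSums(psd$values[low, , drop = FALSE])
  highp <- colSums(psd$values[high, , drop = FALSE])
  ratio <- ifelse(lowp > 0, highp / lowp, Inf)
  maxpsd <- apply(psd$values[low, , drop = FALSE], 2, max)
  fin <- is.finite(ratio)
  structure(
    list(ratio = ratio, maxpsd = maxpsd,
         T_ratio = stats::sd(ratio[fin]), T_maxpsd = stats::sd(maxpsd),
         frame_times = psd$frame_times, axis = "",
         flagged = which(!fin)),
    class = "kinematic_features"
  )
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat(sprintf(
    "<kinematic_features> %d frames; T_ratio = %.3g, T_maxpsd = %.3g\n",
    length(x$ratio), x$T_ratio, x$T_maxpsd))
  invisible(x)
}

#' Convert kinematic features to a tibble
#' @param x A `kinematic_features`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `ratio`, `maxpsd`.
#' @exportS3Method tibble::as_tibble
as_tibble.kinematic_features <- function(x, ...) {
  tibble::tibble(time_ms = x$frame_times, ratio = x$ratio,
                 maxpsd = x$maxpsd)
}

#' Predict potential movements from kinematic features
#'
#' The kinematic early-detection rule: a potential movement is flagged at
#' every frame where *both* `ratio(t) > T_ratio` and
#' `maxpsd(t) > T_maxpsd` (strict inequalities); a run of consecutive
#' qualifying frames collapses to its first frame, the moment the
#' prediction fires.  A run already qualifying at the very first frame has
#' no onset to report and is skipped -- in particular a constant feature
#' pair produces no events.
#'
#' @param feat A `kinematic_features` object.
#' @return Numeric vector of event times in ms.
#' @export
predict_movements <- function(feat) {
  ratio <- feat$ratio
  ratio[!is.finite(ratio)] <- Inf   # infinite ratio still exceeds T_ratio
  qualify <- ratio > feat$T_ratio & feat$maxpsd > feat$T_maxpsd
  if (!any(qualify)) return(numeric(0))
  r <- rle(qualify)
  ends <- cumsum(r$lengths)
  starts <- (ends - r$lengths + 1)[r$values]
  starts <- starts[starts > 1]
  feat$frame_times[starts]
}

#' Kinematic quality parameter
#'
#' Scores kinematic prediction events against the movement list with the
#' same geometric-mean quality parameter as the EEG module.  A kinematic
#' event is a true positive when it falls inside
#' `[extended_start - lead_ms, start)` of some movement: the early-warning
#' span just before and around the mechanical onset.
#'
#' @param events Numeric vector of event times in ms (one axis), or a
#'   named list of such vectors to score several axes plus their
#'   union-combined result.
#' @param movements A `movement_windows` tibble.
#' @param lead_ms Early-warning margin before `extended_start`
#'   (default 500 ms).
#' @param combine Passed to [qp_score()].
#' @return For a single event vector, a `qp_result`.  For a named list, a
#'   tibble with one row per axis plus a `"combined"` row (event union).
#' @export
kinematic_qp <- function(events, movements, lead_ms = 500,
                         combine = "geometric") {
  spans <- data.frame(
    lo = pmax(0, movements$extended_start - lead_ms),
    hi = movements$start
  )
  if (!is.list(events)) return(qp_score(events, spans, combine = combine))
  per_axis <- purrr::imap(events, function(ev, nm) {
    dplyr::mutate(tidy(qp_score(ev, spans, combine = combine)),
                  axis = nm, .before = 1)
  })
  union_ev <- sort(unique(unlist(events)))
  combined <- dplyr::mutate(
    tidy(qp_score(union_ev, spans, combine = combine)),
    axis = paste(names(events), collapse = ""), .before = 1)
  dplyr::bind_rows(c(per_axis, list(combined)))
}
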