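# Welch magnitude-squared coherence of one pair of equal-length segments.
# Sub-windows of `sub_len` samples with `sub_overlap` overlap, Hamming
# tapered, zero-padded to `nfft`; spectra averaged across sub-windows.
# Returns the one-sided coherence vector (length nfft/2 + 1), or NaN when
# either channel is identically zero.
.msc_core <- function(x, y, sub_len = 8, sub_overlap = 6, nfft = 512) {
  n <- length(x)
  stopifnot(length(y) == n)
  step <- sub_len - sub_overlap
  n_sub <- (n - sub_len) %/% step + 1
  if (n_sub < 2 || all(x == 0) || all(y == 0)) {
    return(rep(NaN, nfft / 2 + 1))
  }
  taper <- hamming_window(sub_len)
  idx <- outer(seq_len(sub_len), (seq_len(n_sub) - 1) * step, `+`)
  pad <- matrix(0, nfft - sub_len, n_sub)
  # each sub-window is demeaned before tapering, so a constant offset in
  # either channel cannot leak across the (very wide) sub-window mainlobe
  xm <- matrix(x[idx], sub_len)
  ym <- matrix(y[idx], sub_len)
  xm <- sweep(xm, 2, colMeans(xm))
  ym <- sweep(ym, 2, colMeans(ym))
  X <- stats::mvfft(rbind(xm * taper, pad))
  Y <- stats::mvfft(rbind(ym * taper, pad))
  keep <- seq_len(nfft / 2 + 1)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  pxx <- rowMeans(Mod(X)^2)
  pyy <- rowMeans(Mod(Y)^2)
  pxy <- rowMeans(X * Conj(Y))
  Mod(pxy)^2 / (pxx * pyy)
}

#' Magnitude-squared coherence of one 200 ms segment pair
#'
#' Welch's averaged modified-periodogram coherence
#' \deqn{C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f) P_{yy}(f)}}
#' computed with 8-sample Hamming sub-windows, overlap 6, zero-padded to an
#' FFT length of 512.  Values lie in \[0, 1\]; an all-zero segment yields a
#' flagged `NaN` column (coherence undefined).
#'
#' @param x,y Numeric vectors of equal length (one 200 ms window each, i.e.
#'   200 samples at 1 kHz), or [bci_ts()] objects.
#' @param fs Sampling frequency in Hz used to label the frequency axis
#'   (taken from `x` when it is a [bci_ts()]).
#' @param sub_len,sub_overlap,nfft Welch sub-window parameters.
#' @return A tibble with columns `freq_hz`, `coherence`.
#' @examples
#' s <- sin(2 * pi * 20 * (0:199) / 1000) + rnorm(200, sd = 0.1)
#' msc_segment(s, 2 * s + 5)  # affine copy: coherence 1
#' @export
msc_segment <- function(x, y, fs = 1000, sub_len = 8, sub_overlap = 6,
                        nfft = 512) {
  if (inherits(x, "bci_ts")) { fs <- x$fs; x <- x$samples }
  if (inherits(y, "bci_ts")) y <- y$samples
  cxy <- .msc_core(x, y, sub_len, sub_overlap, nfft)
  tibble::tibble(freq_hz = (seq_along(cxy) - 1) * fs / nfft, coherence = cxy)
}

#' Time-resolved corticomuscular coherence (coherogram)
#'
#' Splits both channels into consecutive non-overlapping 200 ms segments
#' (a trailing partial segment is dropped) and computes the Welch
#' magnitude-squared coherence of each segment pair.
#'
#' @param eeg,emg Synchronized [bci_ts()] at the same rate and length.
#' @param segment_ms Segment length in ms (default 200).
#' @param lowpass Apply the 30 Hz EMG low-pass ([lowpass_emg()]) before
#'   segmenting (default TRUE).
#' @param ... Passed to the Welch core (`sub_len`, `sub_overlap`, `nfft`).
#' @return A list of class `coherogram`: `values` (frequency x segment
#'   matrix in \[0, 1\]), `freqs` (Hz), `segment_times` (segment centers,
#'   ms), `eeg_channel`, `emg_electrode`.
#' @export
coherogram <- function(eeg, emg, segment_ms = 200, lowpass = TRUE, ...) {
  stopifnot(inherits(eeg, "bci_ts"), inherits(emg, "bci_ts"))
  if (eeg$fs != emg$fs) stop("eeg and emg must share one sampling rate",
                             call. = FALSE)
  if (length(eeg$samples) != length(emg$samples)) {
    stop(sprintf("length mismatch: eeg has %d samples, emg has %d",
                 length(eeg$samples), length(emg$samples)), call. = FALSE)
  }
  if (lowpass) emg <- lowpass_emg(emg)
  seg_len <- round(segment_ms * eeg$fs / 1000)
  n_seg <- length(eeg$samples) %/% seg_len
  nfft <- list(...)$nfft %||% 512
  vals <- matrix(NA_real_, nfft / 2 + 1, n_seg)
  for (k in seq_len(n_seg)) {
    i <- ((k - 1) * seg_len + 1):(k * seg_len)
    vals[, k] <- .msc_core(eeg$samples[i], emg$samples[i], ...)
  }
  structure(
    list(values = vals, freqs = (seq_len(nrow(vals)) - 1) * eeg$fs / nfft,
         segment_times = eeg$t0 + ((seq_len(n_seg) - 0.5) * seg_len) *
           1000 / eeg$fs,
         eeg_channel = eeg$label, emg_electrode = emg$label),
    class = "coherogram"
  )
}

#' @export
print.coherogram <- function(x, ...) {
  cat(sprintf("<coherogram> %s x %s: %d frequency bins x %d segments\n",
              x$eeg_channel, x$emg_electrode, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Convert a coherogram to a long tibble
#' @param x A `coherogram`.
#' @param ... Unused.
#' @return Tibble with `freq_hz`, `time_ms`, `coherence`.
#' @exportS3Method tibble::as_tibble
as_tibble.coherogram <- function(x, ...) {
  tibble::tibble(
    freq_hz = rep(x$freqs, times = ncol(x$values)),
    time_ms = rep(x$segment_times, each = length(x$freqs)),
    coherence = as.vector(x$values)
  )
}

#' Probability of stimulation from a coherogram
#'
#' Summarizes the coherogram into a band-mean trace (default 13--30 Hz,
#' the classic corticomuscular beta band), detects segments whose trace
#' exceeds a standard-deviation threshold, and scores them against the
#' movements.  The quality parameter has the same geometric-mean form as
#' the EEG module; the true-positive span of a movement is its extended
#' window together with the 2-s pre-movement period,
#' `[extended_start - premovement_ms, end)`.
#'
#' @param cg A `coherogram`.
#' @param movements A `movement_windows` tibble.
#' @param band Length-2 Hz interval summarized for thresholding.
#' @param c_sd SD multiplier (default 1).
#' @param threshold_rule `"mean_sd"` (mean + c * SD of the trace, default)
#'   or `"sd"` (a bare c * SD threshold).
#' @param premovement_ms Pre-movement span added before `extended_start`.
#' @return A `qp_result` with the band-mean trace attached as attribute
#'   `"trace"` (a tibble `time_ms`, `coherence`, `event`).
#' @export
stimulation_probability <- function(cg, movements, band = c(13, 30),
                                    c_sd = 1,
                                    threshold_rule = c("mean_sd", "sd"),
                                    premovement_ms = 2000) {
  threshold_rule <- match.arg(threshold_rule)
  sel <- cg$freqs >= band[1] & cg$freqs <= band[2]
  trace <- colMeans(cg$values[sel, , drop = FALSE])
  ok <- is.finite(trace)
  thr <- if (threshold_rule == "mean_sd") {
    mean(trace[ok]) + c_sd * stats::sd(trace[ok])
  } else {
    c_sd * stats::sd(trace[ok])
  }
  events <- cg$segment_times[ok & trace > thr]
  spans <- data.frame(
    lo = pmax(0, movements$extended_start - premovement_ms),
    hi = movements$end
  )
  res <- qp_score(events, spans)
  attr(res, "trace") <- tibble::tibble(
    time_ms = cg$segment_times, coherence = trace,
    event = ok & trace > thr
  )
  res
}

#' Enumerate all EEG x EMG electrode pairings
#'
#' The full combinatorial set tested by the corticomuscular module: every
#' EEG montage channel against every electrode of every muscle array
#' (13 x 4 x 16 = 832 pairs with the defaults).
#'
#' @param eeg_channels EEG channel names (default [eeg_montage()]).
#' @param muscles Muscle names (default [emg_muscles()]).
#' @param electrodes_per_muscle Electrodes per array (default 16).
#' @return A tibble with columns `eeg`, `muscle`, `electrode`.
#' @export
enumerate_coherence_pairs <- function(eeg_channels = eeg_montage(),
                                      muscles = emg_muscles(),
                                      electrodes_per_muscle = 16) {
  tidyr::expand_grid(eeg = eeg_channels, muscle = muscles,
                     electrode = seq_len(electrodes_per_muscle))
}
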