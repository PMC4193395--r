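#' Construct a sampled signal
#'
#' The basic container used throughout the package: a numeric sample vector
#' together with its sampling frequency, the start offset of the first sample
#' on the recording timeline, and a channel label.  The time of sample `i`
#' (1-based) is `t0 + (i - 1) * 1000 / fs` milliseconds.
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in ms (default 0).
#' @param label Channel name.
#' @return An object of class `bci_ts`.
#' @examples
#' ts <- bci_ts(sin(2 * pi * 10 * (0:999) / 1000), fs = 1000, label = "C3")
#' ts_duration_ms(ts)
#' @export
bci_ts <- function(samples, fs, t0 = 0, label = "") {
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0)
  if (anyNA(samples)) stop("samples must not contain NA", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)),
    class = "bci_ts"
  )
}

#' @export
print.bci_ts <- function(x, ...) {
  cat(sprintf("<bci_ts> %s: %d samples @ %g Hz (t0 = %g ms, %.3f s)\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$samples), x$fs, x$t0, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.bci_ts <- function(x) length(x$samples)

#' Duration of a signal in milliseconds
#' @param ts A [bci_ts()] object.
#' @return Duration in ms.
#' @export
ts_duration_ms <- function(ts) length(ts$samples) * 1000 / ts$fs

#' Sample times of a signal
#' @param ts A [bci_ts()] object.
#' @return Numeric vector of sample times in ms.
#' @export
ts_times_ms <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) * 1000 / ts$fs

#' Convert a signal to a tibble
#'
#' @param x A [bci_ts()] object.
#' @param ... Unused.
#' @return A tibble with columns `time_ms`, `value`, `channel`.
#' @exportS3Method tibble::as_tibble
as_tibble.bci_ts <- function(x, ...) {
  tibble::tibble(time_ms = ts_times_ms(x), value = x$samples,
                 channel = x$label)
}

#' Resample a signal to a new rate
#'
#' Band-limited polyphase resampling (not sample repetition), so that
#' spectral content below both Nyquist limits is preserved for the
#' spectrogram modules downstream.  Used to bring 256 Hz EEG and 50 Hz
#' gyroscope traces onto the common 1 kHz timeline.
#'
#' @param ts A [bci_ts()] object.
#' @param target_fs Target sampling frequency in Hz.
#' @param filter_half_length Half-length (in output samples) of the
#'   anti-aliasing FIR design; the default meets a 0.1% amplitude error on
#'   pure tones away from the edges.
#' @return A [bci_ts()] at `target_fs` with `round(n * target_fs / fs)`
#'   samples.
#' @examples
#' gyro <- bci_ts(sin(2 * pi * 5 * (0:249) / 50), fs = 50)
#' length(resample_ts(gyro, 1000))  # 100 ms -> x20 samples
#' @export
resample_ts <- function(ts, target_fs, filter_half_length = 10) {
  stopifnot(inherits(ts, "bci_ts"), target_fs > 0)
  if (length(ts$samples) == 0 || ts$fs == target_fs) {
    return(bci_ts(ts$samples, target_fs, ts$t0, ts$label))
  }
  frac <- .as_rational(target_fs / ts$fs)
  y <- signal::resample(ts$samples, frac$p, frac$q, d = filter_half_length)
  n_out <- round(length(ts$samples) * target_fs / ts$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  bci_ts(y, target_fs, ts$t0, ts$label)
}

# small continued-fraction rationalization for fs ratios (e.g. 1000/256)
.as_rational <- function(x, tol = 1e-9, max_den = 1e6) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * x) break
    if (abs(r - a) < 1e-15) break
    r <- 1 / (r - a)
  }
  list(p = p1, q = q1)
}

#' Band-pass filter a signal
#'
#' Zero-phase forward-backward Butterworth filtering (high-pass and low-pass
#' sections applied in cascade).  Zero phase matters here: event timing feeds
#' the quality-parameter windows, so the filter must not delay onsets.
#' The default corners reproduce the 0.5--60 Hz EEG conditioning band.
#'
#' @param ts A [bci_ts()] object.
#' @param lo,hi Passband corners in Hz, `0 <= lo < hi < fs/2`.
#' @param order Butterworth order per section (the forward-backward pass
#'   doubles the effective attenuation).
#' @return Filtered [bci_ts()].
#' @export
bandpass_ts <- function(ts, lo = 0.5, hi = 60, order = 4) {
  stopifnot(inherits(ts, "bci_ts"))
  if (hi >= ts$fs / 2) {
    stop(sprintf("hi = %g Hz must be below Nyquist (%g Hz)", hi, ts$fs / 2),
         call. = FALSE)
  }
  if (lo < 0 || lo >= hi) stop("need 0 <= lo < hi", call. = FALSE)
  if (length(ts$samples) == 0) return(ts)
  x <- ts$samples
  if (lo > 0) {
    hp <- signal::butter(2, lo / (ts$fs / 2), type = "high")
    x <- signal::filtfilt(hp, x)
  }
  lp <- signal::butter(order, hi / (ts$fs / 2), type = "low")
  x <- signal::filtfilt(lp, x)
  bci_ts(x, ts$fs, ts$t0, ts$label)
}

#' Low-pass filter an EMG trace at 30 Hz
#'
#' Surface EMG is low-pass filtered before entering the corticomuscular
#' coherence stage, keeping the band where cortical drive to the muscle is
#' expressed.
#'
#' @param emg A [bci_ts()] object at 1000 Hz.
#' @param cutoff Cutoff frequency in Hz (default 30).
#' @return Filtered [bci_ts()].
#' @export
lowpass_emg <- function(emg, cutoff = 30) {
  stopifnot(inherits(emg, "bci_ts"))
  if (length(emg$samples) == 0) return(emg)
  lp <- signal::butter(4, cutoff / (emg$fs / 2), type = "low")
  bci_ts(signal::filtfilt(lp, emg$samples), emg$fs, emg$t0, emg$label)
}
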