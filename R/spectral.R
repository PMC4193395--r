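#' Hamming window
#' @param n Window length in samples.
#' @return Numeric vector of window coefficients.
#' @keywords internal
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Short-time Fourier transform at arbitrary frequencies (Goertzel)
#'
#' Hamming-windowed STFT evaluated with the Goertzel second-order recursion
#' at exactly the requested frequencies -- not at FFT-grid bins -- so the
#' spectrogram can be asked for integer-Hz rows (1--40 Hz for EEG,
#' 1--20 Hz for the gyroscope) regardless of window length.  Frame `k`
#' (0-based) covers samples `[k*step, k*step + window_len)` with
#' `step = window_len - overlap`; a trailing partial frame is dropped.
#'
#' @param ts A [bci_ts()] object.
#' @param freqs Frequencies in Hz at which to evaluate (each < fs/2).
#' @param window_len Window length in samples (default 256).
#' @param overlap Overlap between consecutive windows in samples
#'   (default 250, i.e. a 6-sample frame step at the defaults).
#' @return A list of class `bci_stft` with elements `S` (complex matrix,
#'   frequency x frame), `freqs`, `frame_times` (frame centers, ms),
#'   `window_len`, `overlap`, `fs`.
#' @examples
#' ts <- bci_ts(sin(2 * pi * 10 * (0:2999) / 1000), fs = 1000)
#' stft <- goertzel_stft(ts, freqs = 1:40)
#' dim(stft$S)
#' @export
goertzel_stft <- function(ts, freqs, window_len = 256, overlap = 250) {
  stopifnot(inherits(ts, "bci_ts"))
  if (overlap < 0 || overlap >= window_len) {
    stop("need 0 <= overlap < window_len", call. = FALSE)
  }
  if (any(freqs >= ts$fs / 2)) {
    stop("all frequencies must be below fs/2", call. = FALSE)
  }
  step <- window_len - overlap
  n <- length(ts$samples)
  if (n < window_len) {
    S <- matrix(complex(real = 0), nrow = length(freqs), ncol = 0)
    frame_times <- numeric(0)
  } else {
    S <- goertzel_stft_cpp(ts$samples, hamming_window(window_len),
                           as.numeric(freqs), ts$fs, as.integer(step))
    k <- 0:(ncol(S) - 1)
    frame_times <- ts$t0 + (k * step + (window_len - 1) / 2) * 1000 / ts$fs
  }
  structure(
    list(S = S, freqs = as.numeric(freqs), frame_times = frame_times,
         window_len = window_len, overlap = overlap, fs = ts$fs),
    class = "bci_stft"
  )
}

#' One-sided power spectral density from an STFT
#'
#' Per-frame PSD in power/Hz, normalized by the sampling rate and the
#' Hamming window energy:
#' \deqn{P(i,j) = \frac{2 |S(i,j)|^2}{F_s \sum_{n=1}^{L} w(n)^2}.}
#'
#' @param stft A `bci_stft` from [goertzel_stft()].
#' @return A list of class `bci_psd` with elements `values` (nonnegative
#'   matrix, frequency bin x time frame), `freqs`, `frame_times`,
#'   `window_len`, `overlap`, `fs`.
#' @export
psd_from_stft <- function(stft) {
  stopifnot(inherits(stft, "bci_stft"))
  w <- hamming_window(stft$window_len)
  P <- 2 * Mod(stft$S)^2 / (stft$fs * sum(w^2))
  structure(
    list(values = P, freqs = stft$freqs, frame_times = stft$frame_times,
         window_len = stft$window_len, overlap = stft$overlap, fs = stft$fs),
    class = "bci_psd"
  )
}

#' Goertzel spectrogram with the pipeline's PSD normalization
#'
#' Convenience wrapper: [goertzel_stft()] followed by [psd_from_stft()].
#'
#' @inheritParams goertzel_stft
#' @return A `bci_psd` object.
#' @export
spectrogram <- function(ts, freqs = 1:40, window_len = 256, overlap = 250) {
  psd_from_stft(goertzel_stft(ts, freqs, window_len, overlap))
}

#' @export
print.bci_psd <- function(x, ...) {
  cat(sprintf(
    "<bci_psd> %d frequency bins (%g-%g Hz) x %d frames, window %d, overlap %d @ %g Hz\n",
    length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$values),
    x$window_len, x$overlap, x$fs))
  invisible(x)
}

#' Convert a PSD matrix to a long tibble
#'
#' @param x A `bci_psd` object.
#' @param ... Unused.
#' @return A tibble with columns `freq_hz`, `time_ms`, `psd`.
#' @exportS3Method tibble::as_tibble
as_tibble.bci_psd <- function(x, ...) {
  tibble::tibble(
    freq_hz = rep(x$freqs, times = ncol(x$values)),
    time_ms = rep(x$frame_times, each = length(x$freqs)),
    psd = as.vector(x$values)
  )
}

#' Write a PSD matrix as CSV (rows = frequency bins, header = frame times)
#' @param psd A `bci_psd` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_psd_csv <- function(psd, path) {
  df <- as.data.frame(psd$values)
  names(df) <- sprintf("%.3f", psd$frame_times)
  df <- cbind(freq_hz = psd$freqs, df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

# Sum of PSD rows over an inclusive frequency band, per frame.
.band_power <- function(psd, band) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) {
    stop(sprintf("band [%g, %g] Hz has no bins in the PSD grid",
                 band[1], band[2]), call. = FALSE)
  }
  colSums(psd$values[sel, , drop = FALSE])
}
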