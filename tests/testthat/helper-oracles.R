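# Independent oracles used across the suite.  These deliberately use naive,
# loop-based formulations so they share no code path with the package.

# Direct windowed DFT of frame k (1-based) at one frequency.
direct_windowed_dft <- function(x, window, k, step, freq, fs) {
  L <- length(window)
  idx <- ((k - 1) * step + 1):((k - 1) * step + L)
  v <- x[idx] * window
  n <- 0:(L - 1)
  sum(v * exp(-2i * pi * freq * n / fs))
}

# Hamming coefficients written out independently of the package helper.
oracle_hamming <- function(n) {
  if (n == 1) return(1)
  k <- seq(0, n - 1)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

# Brute-force Welch magnitude-squared coherence of one segment pair:
# explicit loop over sub-windows, one FFT per sub-window per channel.
oracle_msc <- function(x, y, sub_len = 8, sub_overlap = 6, nfft = 512) {
  step <- sub_len - sub_overlap
  n_sub <- (length(x) - sub_len) %/% step + 1
  taper <- oracle_hamming(sub_len)
  nb <- nfft / 2 + 1
  pxx <- numeric(nb); pyy <- numeric(nb); pxy <- complex(nb)
  for (s in seq_len(n_sub)) {
    i <- ((s - 1) * step + 1):((s - 1) * step + sub_len)
    xs <- x[i] - mean(x[i])
    ys <- y[i] - mean(y[i])
    X <- stats::fft(c(xs * taper, rep(0, nfft - sub_len)))[1:nb]
    Y <- stats::fft(c(ys * taper, rep(0, nfft - sub_len)))[1:nb]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  Mod(pxy / n_sub)^2 / ((pxx / n_sub) * (pyy / n_sub))
}

# Brute-force threshold-crossing scan used against event detectors: every
# maximal run of values strictly above thr that begins after a sub-threshold
# value contributes the index of its maximum.
oracle_peak_indices <- function(v, thr) {
  out <- integer(0)
  i <- 2
  n <- length(v)
  while (i <= n) {
    if (v[i] > thr && v[i - 1] <= thr) {
      j <- i
      while (j < n && v[j + 1] > thr) j <- j + 1
      out <- c(out, (i:j)[which.max(v[i:j])])
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Small multimodal fixture shared by end-to-end tests (kept light: few
# channels, 10 movements).
small_fixture <- function(seed = 42, n_movements = 10) {
  make_multimodal_fixture(
    n_movements = n_movements, seed = seed,
    eeg_channels = c("C3", "CZ"), electrodes_per_muscle = 2
  )
}
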