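#' Generate a full synthetic multimodal recording with ground truth
#'
#' Builds a complete [bci_recording()] emulating one finger-to-nose run of
#' a tremor patient, together with the ground truth needed for end-to-end
#' assertions:
#'
#' * magnetometer: smooth plateaus spanning each movement epoch (the basic
#'   movement-window signal);
#' * accelerometer: activity bursts starting 300 ms before each onset (the
#'   window-extension signal);
#' * gyroscope (y axis): a continuous rest tremor at `tremor_hz` that is
#'   suppressed for the 200 ms directly before each onset (the rest-tremor
#'   decrement), plus a pre-onset burst combining a 3 Hz low-frequency
#'   rise and a 12 Hz high-band component in the 500--200 ms window before
#'   onset (the early-detection signature), plus a slow large-amplitude
#'   voluntary-movement component during the epoch;
#' * EEG: a 10 Hz alpha rhythm attenuated to 0.2 of its amplitude during
#'   each 2-s pre-movement window (the ERD), a constant 22 Hz beta rhythm,
#'   and -- on channel `C3` only -- a 20 Hz component shared with the
#'   first biceps EMG electrode during the pre-movement windows (the
#'   corticomuscular coherence signature);
#' * EMG: white noise on every electrode, with the shared 20 Hz bursts on
#'   `biceps` electrode 1.
#'
#' All channels receive additive white noise with standard deviation
#' `1/snr` relative to the unit-amplitude components.
#'
#' @param n_movements Number of movement epochs (default 10).
#' @param tremor_hz Rest-tremor frequency in Hz (default 5).
#' @param snr Amplitude signal-to-noise ratio (default 10).
#' @param seed Optional integer seed (`set.seed`); equal seeds give
#'   identical fixtures.
#' @param period_ms Onset-to-onset spacing (default 5000 ms).
#' @param movement_ms Movement-epoch duration (default 2000 ms).
#' @param fs Common sampling rate (default 1000 Hz).
#' @param eeg_channels EEG channels to synthesize (default the full
#'   montage; pass fewer for faster tests).
#' @param electrodes_per_muscle EMG electrodes per array (default 16).
#' @return A list with `recording` (a [bci_recording()]) and
#'   `truth`: `onsets` (ms), `movement_end` (ms), `erd_windows`,
#'   `coherent_bursts`, `tremor_gaps`, `kinematic_bursts` (tibbles with
#'   `lo`, `hi` in ms).
#' @export
make_multimodal_fixture <- function(n_movements = 10, tremor_hz = 5,
                                    snr = 10, seed = NULL,
                                    period_ms = 5000, movement_ms = 2000,
                                    fs = 1000,
                                    eeg_channels = eeg_montage(),
                                    electrodes_per_muscle = 16) {
  stopifnot(n_movements >= 1)
  if (period_ms <= movement_ms + 2500) {
    stop("period_ms must exceed movement_ms + 2500 so that pre-movement, ",
         "gap and burst spans do not collide", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  onsets <- period_ms * seq_len(n_movements)
  total_ms <- period_ms * (n_movements + 1)
  n <- round(total_ms * fs / 1000)
  t_ms <- (0:(n - 1)) * 1000 / fs
  noise_sd <- 1 / snr
  noise <- function() stats::rnorm(n, sd = noise_sd)

  # smooth 0/1 gate over [lo, hi) with raised-cosine edges
  gate <- function(lo, hi, ramp = 50) {
    g <- numeric(n)
    for (i in seq_along(lo)) {
      core <- t_ms >= lo[i] + ramp & t_ms < hi[i] - ramp
      g[core] <- 1
      up <- t_ms >= lo[i] & t_ms < lo[i] + ramp
      g[up] <- (1 - cos(pi * (t_ms[up] - lo[i]) / ramp)) / 2
      dn <- t_ms >= hi[i] - ramp & t_ms < hi[i]
      g[dn] <- (1 + cos(pi * (t_ms[dn] - (hi[i] - ramp)) / ramp)) / 2
    }
    g
  }
  move_gate <- gate(onsets, onsets + movement_ms)
  pre_gate <- gate(onsets - 2000, onsets)            # ERD / coherence span
  burst_gate <- gate(onsets - 500, onsets - 200, ramp = 20)
  gap_gate <- gate(onsets - 200, onsets, ramp = 10)  # tremor suppression
  acce_gate <- gate(onsets - 300, onsets + movement_ms)

  phase <- function(f) 2 * pi * f * t_ms / 1000
  tser <- function(x, label) bci_ts(x, fs, 0, label)

  # --- IMU ---------------------------------------------------------------
  mag <- list(
    x = tser(10 * move_gate + noise(), "mag.x"),
    y = tser(noise(), "mag.y"),
    z = tser(noise(), "mag.z")
  )
  acce <- list(
    x = tser(3 * acce_gate * sin(phase(2)) + noise(), "acce.x"),
    y = tser(noise(), "acce.y"),
    z = tser(noise(), "acce.z")
  )
  tremor <- sin(phase(tremor_hz)) * (1 - gap_gate) * (1 - move_gate)
  gyro_y <- tremor +
    3 * burst_gate * sin(phase(3)) +
    4 * burst_gate * sin(phase(12)) +
    2 * move_gate * sin(phase(1.5)) +
    noise()
  gyro <- list(
    x = tser(0.3 * sin(phase(tremor_hz) + 1) + noise(), "gyro.x"),
    y = tser(gyro_y, "gyro.y"),
    z = tser(noise(), "gyro.z")
  )

  # --- EEG ---------------------------------------------------------------
  alpha_env <- 1 - 0.8 * pre_gate       # ERD: alpha down to 0.2 amplitude
  shared20 <- sin(phase(20) + 0.4)
  eeg <- lapply(rlang::set_names(eeg_channels), function(ch) {
    x <- alpha_env * sin(phase(10) + stats::runif(1, 0, 2 * pi)) +
      0.3 * sin(phase(22) + stats::runif(1, 0, 2 * pi)) + noise()
    if (ch == "C3") x <- x + 0.8 * pre_gate * shared20
    tser(x, ch)
  })

  # --- EMG ---------------------------------------------------------------
  emg <- lapply(rlang::set_names(emg_muscles()), function(muscle) {
    lapply(seq_len(electrodes_per_muscle), function(j) {
      x <- stats::rnorm(n)
      if (muscle == "biceps" && j == 1) x <- x + 2 * pre_gate * shared20
      tser(x, sprintf("%s.%02d", muscle, j))
    })
  })

  truth <- list(
    onsets = onsets,
    movement_end = onsets + movement_ms,
    erd_windows = tibble::tibble(lo = onsets - 2000, hi = onsets),
    coherent_bursts = tibble::tibble(lo = onsets - 2000, hi = onsets),
    kinematic_bursts = tibble::tibble(lo = onsets - 500, hi = onsets - 200),
    tremor_gaps = tibble::tibble(lo = onsets - 200, hi = onsets)
  )
  list(
    recording = bci_recording(eeg = eeg, emg = emg,
                              imu = list(gyro = gyro, acce = acce,
                                         mag = mag),
                              fs_common = fs),
    truth = truth
  )
}
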