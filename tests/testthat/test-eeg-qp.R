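flat_psd <- function(value = 1, nframes = 10) {
  stft <- goertzel_stft(bci_ts(rnorm(2000), 1000), 1:40)
  psd <- psd_from_stft(stft)
  psd$values <- matrix(value, length(psd$freqs), nframes)
  psd$frame_times <- seq_len(nframes) * 6
  psd
}

test_that("ratiogram closed forms hold on flat spectra", {
  psd <- flat_psd(1)
  # beta 26-33 Hz: 8 bins; alpha 8-10 Hz: 3 bins
  r1 <- ratiogram(psd, beta_band = c(26, 33), alpha_band = c(8, 10),
                  exponent = 1)
  expect_equal(unique(r1$values), 10 * log10(8 / 3), tolerance = 1e-12)
  r2 <- ratiogram(psd, beta_band = c(26, 33), alpha_band = c(8, 10),
                  exponent = 2)
  expect_equal(unique(r2$values), 10 * log10(64 / 3), tolerance = 1e-12)

  # multiplying alpha power by 10 drops the simple ratio by exactly 10 dB
  psd10 <- psd
  sel <- psd10$freqs >= 8 & psd10$freqs <= 10
  psd10$values[sel, ] <- 10
  r10 <- ratiogram(psd10, beta_band = c(26, 33), alpha_band = c(8, 10))
  expect_equal(unique(r1$values - r10$values), 10, tolerance = 1e-12)
})

test_that("zero alpha power flags frames as infinite", {
  psd <- flat_psd(1)
  psd$values[psd$freqs >= 8 & psd$freqs <= 10, 4] <- 0
  r <- ratiogram(psd, beta_band = c(26, 33), alpha_band = c(8, 10))
  expect_equal(r$flagged, 4L)
  expect_true(is.infinite(r$values[4]))
})

test_that("ratio events are supra-threshold peaks, one per run", {
  mk <- function(v) list(values = v, frame_times = seq_along(v) * 10)
  expect_length(detect_ratio_events(mk(rep(0, 50)), threshold = 1), 0)

  tri <- c(rep(0, 10), seq(0, 5, by = 0.5), seq(4.5, 0, by = -0.5),
           rep(0, 10))
  ev <- detect_ratio_events(mk(tri), threshold = 2)
  expect_length(ev, 1)
  expect_equal(ev, which.max(tri) * 10)

  # matches the brute-force crossing scan on random traces
  set.seed(77)
  for (rep in 1:50) {
    v <- as.numeric(stats::filter(rnorm(300), rep(1 / 5, 5),
                                  sides = 2))
    v[is.na(v)] <- 0
    thr <- stats::quantile(v, 0.8)
    ev <- detect_ratio_events(mk(v), thr)
    expect_equal(ev, oracle_peak_indices(v, thr) * 10)
  }

  # documented operating thresholds are plain valid inputs
  expect_silent(detect_ratio_events(mk(tri), threshold = -4.8))
  expect_silent(detect_ratio_events(mk(tri), threshold = 9.5))
})

test_that("raising the threshold only discards or sharpens events", {
  set.seed(42)
  v <- cumsum(rnorm(500)) / 5
  mk <- list(values = v, frame_times = seq_along(v))
  thresholds <- seq(min(v), max(v), length.out = 30)
  prev_frames <- NULL
  for (th in thresholds) {
    ev <- detect_ratio_events(mk, th)
    # every event value strictly exceeds the threshold
    expect_true(all(v[ev] > th))
    prev_frames <- ev
  }
  # above the global maximum there are no events at all
  expect_length(detect_ratio_events(mk, max(v)), 0)
  # the event count on a single-peak trace is monotone in the threshold
  tri <- c(seq(0, 5, by = 0.1), seq(4.9, 0, by = -0.1))
  counts <- vapply(seq(0.5, 5.5, by = 0.5), function(th) {
    length(detect_ratio_events(list(values = tri,
                                    frame_times = seq_along(tri)), th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quality parameter closed forms are exact", {
  movements <- tibble::tibble(extended_start = c(3000, 8000),
                              start = c(3000, 8000),
                              end = c(5000, 10000))
  class(movements) <- c("movement_windows", class(movements))

  # every event a TP in a distinct movement -> qp = 100
  qp <- eeg_quality_parameter(c(1500, 6500), movements)
  expect_equal(qp$qp, 100)

  # 3 events, 2 TP; 4 movements, 2 predicted -> qp = 100 * sqrt(1/3)
  m4 <- tibble::tibble(extended_start = c(3, 8, 13, 18) * 1000,
                       start = c(3, 8, 13, 18) * 1000,
                       end = c(5, 10, 15, 20) * 1000)
  qp2 <- eeg_quality_parameter(c(1500, 6500, 5500), m4)
  expect_equal(qp2$p, 2 / 3)
  expect_equal(qp2$d, 1 / 2)
  expect_equal(qp2$qp, 100 * sqrt(1 / 3), tolerance = 1e-12)

  # no events -> degenerate zero
  qp0 <- eeg_quality_parameter(numeric(0), movements)
  expect_equal(c(qp0$p, qp0$d, qp0$qp), c(0, 0, 0))

  # zero movements undefined
  expect_error(eeg_quality_parameter(1500, m4[0, ]), "movements")

  # events during execution are false positives unless opted in
  qp_exec <- eeg_quality_parameter(c(1500, 4000), movements)
  expect_equal(qp_exec$p, 1 / 2)
  qp_exec2 <- eeg_quality_parameter(c(1500, 4000), movements,
                                    count_in_movement = TRUE)
  expect_equal(qp_exec2$p, 1)
})

test_that("qp respects geometric-mean bounds and translation invariance", {
  set.seed(11)
  for (rep in 1:20) {
    mov <- sort(runif(5, 5000, 50000))
    movements <- tibble::tibble(extended_start = mov, start = mov,
                                end = mov + 2000)
    ev <- runif(8, 0, 52000)
    qp <- eeg_quality_parameter(ev, movements)
    expect_equal(qp$qp, 100 * sqrt(qp$p * qp$d), tolerance = 1e-12)
    if (qp$p > 0 && qp$d > 0) {
      expect_lte(qp$qp, 100 * max(qp$p, qp$d) + 1e-9)
      expect_gte(qp$qp, 100 * min(qp$p, qp$d) - 1e-9)
    }
    shift <- 3777
    qp_s <- eeg_quality_parameter(
      ev + shift,
      dplyr::mutate(movements,
                    extended_start = extended_start + shift,
                    start = start + shift, end = end + shift))
    expect_equal(tidy(qp_s), tidy(qp))
  }
})

test_that("band-pair scan ranks the ERD-reactive band pair on fixtures", {
  # one-pair catalog -> one row per exponent
  psd <- flat_psd(1, nframes = 50)
  movements <- tibble::tibble(extended_start = 100, start = 100, end = 200)
  one <- band_pair_scan(psd, movements,
                        catalog = list(alpha = list(c(8, 10)),
                                       beta = list(c(26, 33))),
                        exponents = 1)
  expect_equal(nrow(one), 1)

  # fixture with a 10 Hz alpha ERD before each movement: top-ranked rows
  # must use a beta band, and an alpha band containing the reactive 10 Hz
  fx <- small_fixture(seed = 1, n_movements = 8)
  rec <- fx$recording
  w <- detect_basic_windows(rec$imu$mag, rest_segment = c(0, 2000))
  psd <- spectrogram(rec$eeg$CZ, freqs = 1:40)
  scan <- band_pair_scan(psd, w)
  expect_equal(nrow(scan), length(band_catalog()$beta) *
                 length(band_catalog()$alpha) * 2)
  top <- scan[1, ]
  expect_gte(top$qp, 80)
  expect_true(top$alpha_lo <= 10 && top$alpha_hi >= 10)
})
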