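test_that("band segments have the right length and in-band spectra", {
  set.seed(60)
  seg <- generate_band_segment(c(8, 13), duration_s = 8, fs = 250)
  expect_length(seg, 2000)
  expect_equal(seg$fs, 250)

  # periodogram argmax lands inside the requested band across seeds
  for (rep in 1:25) {
    band <- list(c(8, 13), c(13, 40), c(4, 8))[[sample(3, 1)]]
    s <- generate_band_segment(band, 8, 250)
    spec <- Mod(stats::fft(s$samples))^2
    f <- (seq_along(spec) - 1) * 250 / length(spec)
    peak <- f[which.max(spec[f <= 125])]
    expect_gte(peak, band[1] - 0.5)
    expect_lte(peak, band[2] + 0.5)
  }
})

test_that("composite traces superpose 32 s of per-band segments", {
  set.seed(61)
  cfg <- sim_config()
  gen <- generate_eeg(cfg)
  expect_length(gen$composite, 8000)
  expect_equal(sort(names(gen$components)),
               sort(c("delta", "theta", "alpha", "beta", "gamma")))
  # superposition is exactly linear
  expect_equal(gen$composite$samples, Reduce(`+`, gen$components),
               tolerance = 1e-12)
})

test_that("injected desynchronizations attenuate alpha inside events only", {
  set.seed(62)
  cfg <- sim_config(erd_attenuation = 1e-6, ramp_s = 0.1)
  a_in_sum <- 0
  a_out_sum <- 0
  for (rep in 1:3) {
    gen <- generate_eeg(cfg)
    inj <- inject_erd(gen, cfg)
    expect_equal(nrow(inj$events), 4)
    durations <- inj$events$end_s - inj$events$start_s
    expect_true(all(durations >= 2 & durations <= 4))
    # non-overlapping and sorted
    expect_true(all(inj$events$start_s[-1] >= inj$events$end_s[-4]))

    # mid-alpha PSD (10-11 Hz: two Hamming mainlobe widths from the band
    # edges, so only sidelobe leakage of the other bands remains) drops
    # inside events; frames 0.7 s from the edges keep the 1.024 s window
    # clear of the cosine ramps
    psd <- spectrogram(inj$composite, freqs = 8:13, window_len = 256,
                       overlap = 250)
    centers <- psd$frame_times / 1000
    inside <- vapply(centers, function(t) {
      any(t >= inj$events$start_s + 0.7 & t < inj$events$end_s - 0.7)
    }, logical(1))
    outside <- vapply(centers, function(t) {
      all(t < inj$events$start_s - 0.7 | t > inj$events$end_s + 0.7)
    }, logical(1))
    mid <- psd$freqs %in% c(10, 11)
    a_in_sum <- a_in_sum +
      mean(colSums(psd$values[mid, inside, drop = FALSE]))
    a_out_sum <- a_out_sum +
      mean(colSums(psd$values[mid, outside, drop = FALSE]))
  }
  expect_lt(a_in_sum, a_out_sum * 10^(-20 / 10))
})

test_that("the simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config()
  set.seed(63); t1 <- erd_trial(cfg)
  set.seed(63); t2 <- erd_trial(cfg)
  expect_identical(t1$composite$samples, t2$composite$samples)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$ratio_simple$values, t2$ratio_simple$values)

  fx1 <- make_multimodal_fixture(n_movements = 2, seed = 99,
                                 eeg_channels = "C3",
                                 electrodes_per_muscle = 1)
  fx2 <- make_multimodal_fixture(n_movements = 2, seed = 99,
                                 eeg_channels = "C3",
                                 electrodes_per_muscle = 1)
  expect_identical(fx1$recording$imu$gyro$y$samples,
                   fx2$recording$imu$gyro$y$samples)
  expect_identical(fx1$recording$eeg$C3$samples,
                   fx2$recording$eeg$C3$samples)
})

test_that("threshold sweep curves vanish at both grid extremes", {
  set.seed(64)
  cur <- qp_threshold_sweep(sim_config(), n_trials = 20)
  for (e in 1:2) {
    sub <- cur[cur$exponent == e, ]
    expect_equal(sub$qp_mean[1], 0)
    expect_equal(sub$qp_mean[nrow(sub)], 0)
    expect_true(all(sub$qp_mean >= 0 & sub$qp_mean <= 100))
    # CI encloses the mean
    expect_true(all(sub$ci_lo <= sub$qp_mean + 1e-9))
    expect_true(all(sub$ci_hi >= sub$qp_mean - 1e-9))
  }
  expect_equal(attr(cur, "n_trials"), 20)
  expect_equal(nrow(cur), 2 * 201)
})

test_that("halving the trial count moves the plateau by less than 2 SE", {
  set.seed(65)
  cfg <- sim_config()
  full <- qp_threshold_sweep(cfg, n_trials = 120)
  half <- qp_threshold_sweep(cfg, n_trials = 60)
  s_full <- full[full$exponent == 1, ]
  k_star <- s_full$k[which.max(s_full$qp_mean)]
  se_half <- half$qp_sd[half$exponent == 1 & half$k == k_star] / sqrt(60)
  se_full <- s_full$qp_sd[s_full$k == k_star] / sqrt(120)
  diff_pl <- abs(qp_plateau(full) - qp_plateau(half))
  expect_lt(diff_pl, 2 * (se_half + se_full) + 1)
})

test_that("fixture construction honours its requested geometry", {
  fx <- make_multimodal_fixture(n_movements = 3, seed = 7,
                                eeg_channels = c("C3", "CZ"),
                                electrodes_per_muscle = 2)
  rec <- fx$recording
  expect_length(rec$eeg, 2)
  expect_length(rec$emg, 4)
  expect_length(rec$emg$biceps, 2)
  expect_equal(fx$truth$onsets, c(5000, 10000, 15000))
  w <- detect_basic_windows(rec$imu$mag, rest_segment = c(0, 2000))
  expect_equal(nrow(w), 3)
  expect_error(make_multimodal_fixture(n_movements = 2, period_ms = 3000),
               "period_ms")
})
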