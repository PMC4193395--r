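#' Configuration of the artificial-EEG simulation
#'
#' Study conditions for the threshold-vs-quality-parameter simulation:
#' 32 s of artificial EEG at 250 Hz built, band by band, from sums of four
#' random sinusoids per 8-s segment (fresh frequencies and phases each
#' segment, i.e. a phase reset at segment boundaries), with four
#' desynchronization events of 2--4 s injected as multiplicative alpha
#' attenuation.
#'
#' @param fs Sampling frequency in Hz (default 250).
#' @param bands Named list of band ranges in Hz.
#' @param segment_s Segment length in s (default 8).
#' @param total_s Total duration in s (default 32, a multiple of
#'   `segment_s`).
#' @param n_sinusoids Sinusoids per band segment (default 4).
#' @param amplitudes Per-sinusoid amplitude, one value or one per band
#'   (default 1 for every band).
#' @param n_erd Number of desynchronization events (default 4).
#' @param erd_duration_s Length-2 range of event durations in s
#'   (default `c(2, 4)`).
#' @param erd_attenuation Multiplicative alpha attenuation inside events,
#'   in (0, 1) -- smaller is deeper ERD (default 0.2).
#' @param ramp_s Raised-cosine ramp at event edges in s (default 0.1).
#' @param spectro_freqs Spectrogram frequency grid in Hz (default 0.5 Hz
#'   plus integer bins up to 44 Hz).
#' @param window_len,overlap Spectrogram window parameters.
#' @param ratio_beta,ratio_alpha Band pair of the ratio traces.  Defaults
#'   to the narrow reactive sub-band pair 26--33 Hz over 8--10 Hz, whose
#'   trace operating range is consistent with the documented example
#'   detection thresholds (about -4.8 dB simple / 9.5 dB squared); see the
#'   methods vignette.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 250,
                       bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                    alpha = c(8, 13), beta = c(13, 40),
                                    gamma = c(36, 44)),
                       segment_s = 8, total_s = 32, n_sinusoids = 4,
                       amplitudes = 1, n_erd = 4,
                       erd_duration_s = c(2, 4), erd_attenuation = 0.2,
                       ramp_s = 0.1,
                       spectro_freqs = c(0.5, 1:44),
                       window_len = 256, overlap = 250,
                       ratio_beta = c(26, 33), ratio_alpha = c(8, 10)) {
  stopifnot(total_s %% segment_s == 0,
            erd_attenuation > 0, erd_attenuation < 1)
  if (length(amplitudes) == 1) {
    amplitudes <- rlang::set_names(rep(amplitudes, length(bands)),
                                   names(bands))
  }
  structure(
    list(fs = fs, bands = bands, segment_s = segment_s, total_s = total_s,
         n_sinusoids = n_sinusoids, amplitudes = amplitudes, n_erd = n_erd,
         erd_duration_s = erd_duration_s, erd_attenuation = erd_attenuation,
         ramp_s = ramp_s, spectro_freqs = spectro_freqs,
         window_len = window_len, overlap = overlap,
         ratio_beta = ratio_beta, ratio_alpha = ratio_alpha),
    class = "sim_config"
  )
}

# plain numeric band segment (fast path used by the sweep)
.band_segment <- function(band, duration_s, fs, n_sinusoids = 4,
                          amplitude = 1) {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  f <- stats::runif(n_sinusoids, band[1], band[2])
  ph <- stats::runif(n_sinusoids, 0, 2 * pi)
  x <- numeric(length(t))
  for (i in seq_len(n_sinusoids)) {
    x <- x + amplitude * sin(2 * pi * f[i] * t + ph[i])
  }
  x
}

#' Generate one band-limited segment of artificial EEG
#'
#' A sum of `n_sinusoids` sinusoids with frequencies drawn uniformly from
#' the band and phases uniform on `[0, 2*pi)`.  Deterministic for a fixed
#' RNG state (`set.seed`).
#'
#' @param band Length-2 Hz interval (inside `(0, fs/2)`).
#' @param duration_s Duration in s.
#' @param fs Sampling frequency in Hz.
#' @param n_sinusoids Number of sinusoids (default 4).
#' @param amplitude Per-sinusoid amplitude (default 1).
#' @return A [bci_ts()].
#' @export
generate_band_segment <- function(band, duration_s, fs, n_sinusoids = 4,
                                  amplitude = 1) {
  stopifnot(band[1] > 0 || band[1] == 0.5 || band[1] >= 0,
            band[2] < fs / 2)
  bci_ts(.band_segment(band, duration_s, fs, n_sinusoids, amplitude), fs,
         label = sprintf("%g-%g Hz", band[1], band[2]))
}

#' Generate an artificial EEG trace
#'
#' For each configured band, consecutive segments of `segment_s` seconds
#' are synthesized independently (so oscillation phase resets at the
#' segment boundaries) and concatenated to `total_s` seconds; the
#' composite trace is the superposition of the bands.  Per-band components
#' are returned so a desynchronization can later be injected into one band
#' alone.
#'
#' @param cfg A [sim_config()].
#' @return A list with `components` (named list of numeric vectors, one
#'   per band), `composite` (a [bci_ts()]) and `fs`.
#' @export
generate_eeg <- function(cfg) {
  n_seg <- cfg$total_s / cfg$segment_s
  components <- lapply(rlang::set_names(names(cfg$bands)), function(b) {
    unlist(lapply(seq_len(n_seg), function(k) {
      .band_segment(cfg$bands[[b]], cfg$segment_s, cfg$fs,
                    cfg$n_sinusoids, cfg$amplitudes[[b]])
    }), use.names = FALSE)
  })
  composite <- Reduce(`+`, components)
  list(components = components,
       composite = bci_ts(composite, cfg$fs, label = "artificial EEG"),
       fs = cfg$fs)
}

# sample n non-overlapping (start, end) intervals inside [0, total_s]
.place_erd_events <- function(cfg) {
  for (attempt in seq_len(1000)) {
    dur <- stats::runif(cfg$n_erd, cfg$erd_duration_s[1],
                        cfg$erd_duration_s[2])
    start <- stats::runif(cfg$n_erd, 0, cfg$total_s - dur)
    ord <- order(start)
    start <- start[ord]; dur <- dur[ord]
    if (cfg$n_erd < 2 || all(start[-1] >= (start + dur)[-cfg$n_erd])) {
      return(tibble::tibble(start_s = start, end_s = start + dur))
    }
  }
  stop(paste("could not place non-overlapping desynchronization events",
             "after 1000 attempts; use shorter durations"), call. = FALSE)
}

#' Inject desynchronization events into an artificial EEG
#'
#' Places `n_erd` non-overlapping intervals (durations uniform in
#' `erd_duration_s`, positions uniform over the trace, rejection-sampled
#' for non-overlap) and multiplies the alpha component by
#' `erd_attenuation` inside them, with raised-cosine ramps of `ramp_s`
#' seconds at the edges -- the standard multiplicative model of an
#' event-related desynchronization.
#'
#' @param gen Output of [generate_eeg()].
#' @param cfg The [sim_config()] used to generate it.
#' @return A list with `composite` (a [bci_ts()] with the attenuated
#'   alpha), `events` (tibble `start_s`, `end_s` of ground-truth
#'   intervals) and `envelope` (the per-sample alpha gain).
#' @export
inject_erd <- function(gen, cfg) {
  events <- .place_erd_events(cfg)
  n <- length(gen$components$alpha)
  t <- (0:(n - 1)) / cfg$fs
  env <- rep(1, n)
  a <- cfg$erd_attenuation
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; e <- events$end_s[i]
    inside <- t >= s & t < e
    env[inside] <- a
    if (cfg$ramp_s > 0) {
      ramp_in <- t >= s & t < s + cfg$ramp_s
      env[ramp_in] <- a + (1 - a) *
        (1 + cos(pi * (t[ramp_in] - s) / cfg$ramp_s)) / 2
      ramp_out <- t >= e - cfg$ramp_s & t < e
      env[ramp_out] <- a + (1 - a) *
        (1 - cos(pi * (t[ramp_out] - (e - cfg$ramp_s)) / cfg$ramp_s)) / 2
    }
  }
  others <- Reduce(`+`, gen$components[names(gen$components) != "alpha"])
  composite <- others + gen$components$alpha * env
  list(composite = bci_ts(composite, cfg$fs, label = "artificial EEG + ERD"),
       events = events, envelope = env)
}

#' Run one simulation trial
#'
#' Generates an artificial EEG, injects desynchronization events, and
#' computes the spectrogram and both ratio traces (simple and squared).
#'
#' @param cfg A [sim_config()].
#' @return A list with `composite`, `events`, `ratio_simple`,
#'   `ratio_squared` (both `ratio_trace` objects) and `erd_id` (integer
#'   per frame: which event contains the frame center, 0 if none).
#' @export
erd_trial <- function(cfg) {
  gen <- generate_eeg(cfg)
  inj <- inject_erd(gen, cfg)
  psd <- spectrogram(inj$composite, freqs = cfg$spectro_freqs,
                     window_len = cfg$window_len, overlap = cfg$overlap)
  r1 <- ratiogram(psd, cfg$ratio_beta, cfg$ratio_alpha, exponent = 1)
  r2 <- ratiogram(psd, cfg$ratio_beta, cfg$ratio_alpha, exponent = 2)
  centers_s <- psd$frame_times / 1000
  erd_id <- integer(length(centers_s))
  for (i in seq_len(nrow(inj$events))) {
    erd_id[centers_s >= inj$events$start_s[i] &
             centers_s < inj$events$end_s[i]] <- i
  }
  list(composite = inj$composite, events = inj$events,
       ratio_simple = r1, ratio_squared = r2, erd_id = erd_id)
}

#' Sweep the detection threshold against the quality parameter
#'
#' The Monte-Carlo study relating the ERD detection threshold to the
#' quality parameter.  Per trial: a fresh artificial EEG with injected
#' desynchronization events; for each threshold `mean + k * SD` of the
#' ratio trace (`k` from -10 to 10 in steps of 0.1, 201 grid points),
#' supra-threshold peaks are detected, counted as true positives when they
#' fall inside a ground-truth event, and summarized as
#' `qp = 100 * sqrt(p * d)`.  Curves are averaged across trials with SD
#' and a normal-theory 95% CI.
#'
#' @param cfg A [sim_config()].
#' @param n_trials Number of Monte-Carlo trials.
#' @param k_grid Threshold grid in SD units (default
#'   `seq(-10, 10, by = 0.1)`).
#' @return A tibble of class `qp_curve` with columns `k`, `exponent`
#'   (1 = simple, 2 = squared ratio), `qp_mean`, `qp_sd`, `ci_lo`,
#'   `ci_hi` (all in percent), and attributes `n_trials`, `config`.
#' @export
qp_threshold_sweep <- function(cfg = sim_config(), n_trials = 300,
                               k_grid = seq(-10, 10, by = 0.1)) {
  stopifnot(n_trials >= 1)
  nk <- length(k_grid)
  acc1 <- matrix(0, nk, 2)  # running sum and sum of squares, simple
  acc2 <- matrix(0, nk, 2)  # squared ratio
  for (trial in seq_len(n_trials)) {
    tr <- erd_trial(cfg)
    for (exp_i in 1:2) {
      trace <- if (exp_i == 1) tr$ratio_simple$values else
        tr$ratio_squared$values
      fin <- is.finite(trace)
      thr <- mean(trace[fin]) + k_grid * stats::sd(trace[fin])
      qp <- sweep_qp_cpp(trace, as.integer(tr$erd_id),
                         nrow(tr$events), thr)[, 3]
      if (exp_i == 1) {
        acc1[, 1] <- acc1[, 1] + qp; acc1[, 2] <- acc1[, 2] + qp^2
      } else {
        acc2[, 1] <- acc2[, 1] + qp; acc2[, 2] <- acc2[, 2] + qp^2
      }
    }
  }
  summarize_acc <- function(acc, exponent) {
    m <- acc[, 1] / n_trials
    v <- pmax(0, acc[, 2] / n_trials - m^2) * n_trials /
      max(1, n_trials - 1)
    se <- sqrt(v / n_trials)
    tibble::tibble(k = k_grid, exponent = exponent, qp_mean = m,
                   qp_sd = sqrt(v), ci_lo = m - 1.96 * se,
                   ci_hi = m + 1.96 * se)
  }
  out <- dplyr::bind_rows(summarize_acc(acc1, 1), summarize_acc(acc2, 2))
  attr(out, "n_trials") <- n_trials
  attr(out, "config") <- cfg
  class(out) <- c("qp_curve", class(out))
  out
}

#' Plateau level of a quality-parameter curve
#'
#' The headline number of the simulation study: the peak of the
#' trial-averaged quality parameter over the threshold grid.  The mean
#' curve is lightly smoothed (moving average over `smooth_k` grid points,
#' i.e. 0.9 SD units at the default grid) before taking the maximum, so
#' the plateau estimate is not inflated by Monte-Carlo noise at small
#' trial counts.
#'
#' @param curve A `qp_curve` from [qp_threshold_sweep()].
#' @param exponent Which ratio (1 = simple, default; 2 = squared).
#' @param smooth_k Moving-average length in grid points (odd; default 9).
#' @return The plateau value in percent.
#' @export
qp_plateau <- function(curve, exponent = 1, smooth_k = 9) {
  m <- curve$qp_mean[curve$exponent == exponent]
  if (smooth_k > 1 && length(m) >= smooth_k) {
    sm <- stats::filter(m, rep(1 / smooth_k, smooth_k), sides = 2)
    m <- sm[!is.na(sm)]
  }
  max(m)
}

#' @rdname qp_threshold_sweep
#' @param x A `qp_curve`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.qp_curve <- function(x, ...) {
  tibble::tibble(
    n_trials = attr(x, "n_trials"),
    plateau_simple = qp_plateau(x, 1),
    plateau_squared = qp_plateau(x, 2)
  )
}

#' Export a quality-parameter curve as wide CSVs
#'
#' Writes one row per trial-aggregate statistic with one column per
#' threshold (mirroring the deposited per-threshold layout), one file per
#' ratio exponent.
#'
#' @param curve A `qp_curve`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_qp_curve_csv <- function(curve, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "QPs.csv"), file.path(dir, "QPsq.csv"))
  for (exp_i in 1:2) {
    sub <- curve[curve$exponent == exp_i, ]
    wide <- as.data.frame(rbind(sub$qp_mean, sub$qp_sd, sub$ci_lo,
                                sub$ci_hi))
    names(wide) <- sprintf("k_%+.1f", sub$k)
    wide <- cbind(statistic = c("mean", "sd", "ci_lo", "ci_hi"), wide)
    readr::write_csv(tibble::as_tibble(wide), paths[exp_i],
                     progress = FALSE)
  }
  invisible(paths)
}
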