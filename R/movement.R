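#' Detect voluntary-movement windows from the magnetometer
#'
#' The magnetometer gives the cleanest on/off picture of a reaching
#' movement, so it defines the basic movement window.  The vector magnitude
#' of the baseline-subtracted triaxial signal is smoothed with a short
#' moving average (an envelope, so single noise samples cannot open a
#' window) and compared against the rest-segment mean of that envelope
#' plus `k` times its rest-segment standard deviation; a window opens on
#' the first supra-threshold sample and closes when the envelope stays
#' sub-threshold for at least `min_gap_ms`.  Windows separated by less
#' than `min_gap_ms` are merged.
#'
#' @param mag List of three axis [bci_ts()] (`x`, `y`, `z`).
#' @param rest_segment Length-2 numeric `(start_ms, end_ms)` of a segment
#'   known to contain no movement; at least 1 s long.  Default: the first
#'   second of the recording (the deposited runs start with a silent lead-in).
#' @param k Threshold multiplier on the rest-segment SD (default 3).
#' @param min_gap_ms Minimum sub-threshold gap closing a window, and the
#'   merge distance between windows (default 500 ms).
#' @param smooth_ms Length of the envelope moving average (default 50 ms).
#' @param min_duration_ms Windows shorter than this after merging are
#'   discarded as noise excursions; a voluntary reaching movement lasts
#'   much longer (default 200 ms).
#' @return A tibble of class `movement_windows` with columns
#'   `extended_start`, `start`, `end` (ms) and `source_axes` (list column);
#'   sorted, non-overlapping.  `extended_start == start` until
#'   [extend_windows()] runs.
#' @examples
#' t <- 0:19999
#' mx <- bci_ts(as.numeric(t >= 5000 & t < 7000) * 10, fs = 1000)
#' m0 <- bci_ts(numeric(20000), fs = 1000)
#' detect_basic_windows(list(x = mx, y = m0, z = m0),
#'                      rest_segment = c(0, 2000))
#' @export
detect_basic_windows <- function(mag, rest_segment = c(0, 1000), k = 3,
                                 min_gap_ms = 500, smooth_ms = 50,
                                 min_duration_ms = 200) {
  stopifnot(length(mag) == 3)
  fs <- mag[[1]]$fs
  if (diff(rest_segment) < 1000) {
    stop("rest_segment must be at least 1 s long for a reliable SD",
         call. = FALSE)
  }
  times <- ts_times_ms(mag[[1]])
  rest_idx <- which(times >= rest_segment[1] & times < rest_segment[2])
  dev2 <- 0
  for (ax in mag) {
    baseline <- mean(ax$samples[rest_idx])
    dev2 <- dev2 + (ax$samples - baseline)^2
  }
  raw <- sqrt(dev2)
  envelope <- .moving_average(raw, max(1, round(smooth_ms * fs / 1000)))
  # threshold statistics come from the raw rest magnitude (the signal's own
  # variability); the smoothed envelope is what crosses it, so isolated
  # noise samples cannot open or chain windows
  thr <- mean(raw[rest_idx]) + k * stats::sd(raw[rest_idx])
  above <- envelope > thr
  if (!any(above)) return(.empty_windows())

  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- tibble::tibble(start = times[starts_i[r$values]],
                         end = times[ends_i[r$values]] + 1000 / fs)
  # close a window only after a sub-threshold gap of min_gap_ms: merge runs
  # whose separation is below min_gap_ms
  merged <- list(c(runs$start[1], runs$end[1]))
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start[i] - last[2] < min_gap_ms) {
        merged[[length(merged)]][2] <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- c(runs$start[i], runs$end[i])
      }
    }
  }
  merged <- Filter(function(w) w[2] - w[1] >= min_duration_ms, merged)
  if (length(merged) == 0) return(.empty_windows())
  out <- tibble::tibble(
    extended_start = vapply(merged, `[`, numeric(1), 1),
    start = vapply(merged, `[`, numeric(1), 1),
    end = vapply(merged, `[`, numeric(1), 2),
    source_axes = rep(list("mag"), length(merged))
  )
  class(out) <- c("movement_windows", class(out))
  out
}

# centered moving average with edge truncation (shorter effective window
# at the ends, so no NA padding)
.moving_average <- function(x, n) {
  if (n <= 1) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2
  i <- seq_along(x)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.empty_windows <- function() {
  out <- tibble::tibble(extended_start = numeric(0), start = numeric(0),
                        end = numeric(0), source_axes = list())
  class(out) <- c("movement_windows", class(out))
  out
}

#' Extend movement windows backward with accelerometer/gyroscope onsets
#'
#' The magnetometer lags the true mechanical onset; accelerometer and
#' gyroscope channels react earlier.  For each window, the 500 ms before
#' `start` is scanned and `extended_start` becomes the earliest time in
#' that span at which any accelerometer or gyroscope channel starts a
#' sustained deviation from its rest mean by more than one rest-segment SD
#' of that channel.  "Sustained" means at least `min_run_ms` consecutive
#' supra-SD samples, so a single noise sample cannot extend a window while
#' the reported onset stays sample-accurate.  `start` and `end` are never
#' moved.
#'
#' @param windows A `movement_windows` tibble from [detect_basic_windows()].
#' @param acce,gyro Lists of three axis [bci_ts()] (either may be NULL).
#' @param rest_segment As in [detect_basic_windows()].
#' @param max_extension_ms Scan depth before `start` (default 500 ms).
#' @param min_run_ms Minimum duration of a supra-SD run to count as a
#'   variation (default 10 ms).
#' @return The windows tibble with updated `extended_start` and
#'   `source_axes`.
#' @export
extend_windows <- function(windows, acce = NULL, gyro = NULL,
                           rest_segment = c(0, 1000),
                           max_extension_ms = 500, min_run_ms = 10) {
  channels <- c(
    if (!is.null(acce)) rlang::set_names(acce, paste0("acce.", names(acce))),
    if (!is.null(gyro)) rlang::set_names(gyro, paste0("gyro.", names(gyro)))
  )
  if (length(channels) == 0 || nrow(windows) == 0) return(windows)
  fs <- channels[[1]]$fs
  min_run <- max(1, round(min_run_ms * fs / 1000))
  times <- ts_times_ms(channels[[1]])
  rest_idx <- which(times >= rest_segment[1] & times < rest_segment[2])
  devs <- lapply(channels, function(ch) {
    mu <- mean(ch$samples[rest_idx])
    s <- stats::sd(ch$samples[rest_idx])
    above <- abs(ch$samples - mu) > s
    # keep only samples belonging to a run of >= min_run supra-SD samples
    r <- rle(above)
    r$values <- r$values & r$lengths >= min_run
    inverse.rle(r)
  })
  for (i in seq_len(nrow(windows))) {
    lo <- windows$start[i] - max_extension_ms
    span <- which(times >= lo & times < windows$start[i])
    ext <- windows$start[i]
    axes <- windows$source_axes[[i]]
    for (nm in names(devs)) {
      hit <- span[devs[[nm]][span]]
      if (length(hit) > 0) {
        first_t <- times[hit[1]]
        if (first_t < ext) ext <- first_t
        axes <- union(axes, nm)
      }
    }
    windows$extended_start[i] <- ext
    windows$source_axes[[i]] <- axes
  }
  windows
}

#' The pre-movement window of a movement
#'
#' Cortical motor preparation is looked for in the 2 s preceding movement
#' onset; detectors count an event as a true positive when it falls inside
#' this interval.
#'
#' @param start Movement onset(s) in ms (vectorized).
#' @param duration_ms Window length (default 2000 ms).
#' @return A tibble with columns `pre_start`, `pre_end` (`[pre_start,
#'   pre_end)`), clipped at time 0.
#' @examples
#' premovement_window(5000)  # [3000, 5000)
#' @export
premovement_window <- function(start, duration_ms = 2000) {
  tibble::tibble(pre_start = pmax(0, start - duration_ms), pre_end = start)
}
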