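#' Standard 13-channel EEG montage over the sensorimotor strip
#'
#' Recording electrodes of the 10--20 system used by the movement-intention
#' pipeline (ground and reference electrodes are not signal channels).
#'
#' @return Character vector of 13 channel names.
#' @export
eeg_montage <- function() {
  c("FC3", "FCz", "FC4", "C5", "C3", "C1", "CZ", "C2", "C4", "C6",
    "CP3", "CPZ", "CP4")
}

#' Muscles carrying the EMG electrode arrays
#' @return Character vector of muscle names.
#' @export
emg_muscles <- function() c("FCR", "ECR", "biceps", "triceps")

#' Assemble a synchronized multichannel recording
#'
#' Container for one run: EEG channels, per-muscle EMG electrode arrays and
#' triaxial inertial sensors, all on a common timeline.  All series are
#' resampled to `fs_common` on construction.
#'
#' @param eeg Named list of [bci_ts()] (names from [eeg_montage()]).
#' @param emg Named list (muscle) of lists of up to 16 electrode [bci_ts()].
#' @param imu Named list with elements `gyro`, `acce`, `mag`, each a list of
#'   three axis [bci_ts()] named `x`, `y`, `z`.
#' @param fs_common Common sampling frequency in Hz (default 1000).
#' @return An object of class `bci_recording`.
#' @export
bci_recording <- function(eeg = list(), emg = list(), imu = list(),
                          fs_common = 1000) {
  resync <- function(ts) {
    if (ts$fs != fs_common) resample_ts(ts, fs_common) else ts
  }
  eeg <- lapply(eeg, resync)
  emg <- lapply(emg, function(arr) {
    if (length(arr) > 16) stop("an EMG array has at most 16 electrodes",
                               call. = FALSE)
    lapply(arr, resync)
  })
  imu <- lapply(imu, function(axes) lapply(axes, resync))
  structure(list(eeg = eeg, emg = emg, imu = imu, fs_common = fs_common),
            class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  n_emg <- sum(vapply(x$emg, length, integer(1)))
  cat(sprintf(
    "<bci_recording> %d EEG channels, %d EMG electrodes (%d muscles), %d IMU sensors @ %g Hz\n",
    length(x$eeg), n_emg, length(x$emg), length(x$imu), x$fs_common))
  invisible(x)
}

# Read one numeric CSV (one column per channel, rows = samples).  A single
# header row is auto-detected by a numeric test on the first line.
.read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells))))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_names = has_header,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  ))  # parse problems are re-raised as structured errors below
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("non-numeric cell in %s at data row %d, column %d",
                 basename(path), probs$row[1], probs$col[1]), call. = FALSE)
  }
  m <- as.matrix(df)
  if (!has_header) colnames(m) <- NULL
  m
}

#' Read a multichannel recording from CSV files
#'
#' Reads the deposited file layout: one CSV per device, one column per
#' channel, rows = samples.  EEG columns are mapped in file order onto
#' `eeg_channels`; IMU files must have three columns (x, y, z); EMG files
#' contribute one electrode per column.  Missing (NULL) paths yield an
#' empty -- not absent -- channel group.  All series are resampled to 1 kHz.
#'
#' @param eeg_path Path to the EEG CSV, or NULL.
#' @param emg_paths Named list (muscle name -> path) of EMG CSVs.
#' @param imu_paths Named list (sensor in `gyro`, `acce`, `mag` -> path).
#' @param eeg_channels Channel-name list the EEG file must match
#'   (default [eeg_montage()]); a column-count mismatch is an error unless
#'   an override list of the right length is supplied.
#' @param eeg_fs,emg_fs,imu_fs Native sampling frequencies of the files
#'   (deposited CSVs are already at 1000 Hz).
#' @return A [bci_recording()] at 1000 Hz.
#' @export
read_recording <- function(eeg_path = NULL, emg_paths = list(),
                           imu_paths = list(),
                           eeg_channels = eeg_montage(),
                           eeg_fs = 1000, emg_fs = 1000, imu_fs = 1000) {
  eeg <- list()
  if (!is.null(eeg_path)) {
    m <- .read_signal_csv(eeg_path)
    if (ncol(m) != length(eeg_channels)) {
      stop(sprintf(
        "EEG file %s has %d columns but the declared montage has %d channels",
        basename(eeg_path), ncol(m), length(eeg_channels)), call. = FALSE)
    }
    nm <- if (!is.null(colnames(m))) colnames(m) else eeg_channels
    eeg <- lapply(seq_len(ncol(m)), function(j) {
      bci_ts(m[, j], eeg_fs, label = nm[j])
    })
    names(eeg) <- nm
  }
  emg <- lapply(rlang::set_names(names(emg_paths) %||% character(0)),
                function(muscle) {
    m <- .read_signal_csv(emg_paths[[muscle]])
    if (ncol(m) > 16) {
      stop(sprintf("EMG file %s has %d columns; arrays have at most 16",
                   basename(emg_paths[[muscle]]), ncol(m)), call. = FALSE)
    }
    lapply(seq_len(ncol(m)), function(j) {
      bci_ts(m[, j], emg_fs, label = sprintf("%s.%02d", muscle, j))
    })
  })
  imu <- lapply(rlang::set_names(names(imu_paths) %||% character(0)),
                function(sensor) {
    m <- .read_signal_csv(imu_paths[[sensor]])
    if (ncol(m) != 3) {
      stop(sprintf("IMU file %s has %d columns; expected 3 (x, y, z)",
                   basename(imu_paths[[sensor]]), ncol(m)), call. = FALSE)
    }
    fs <- if (length(imu_fs) > 1) imu_fs[[sensor]] else imu_fs
    axes <- lapply(1:3, function(j) {
      bci_ts(m[, j], fs, label = paste0(sensor, ".", c("x", "y", "z")[j]))
    })
    names(axes) <- c("x", "y", "z")
    axes
  })
  bci_recording(eeg = eeg, emg = emg, imu = imu, fs_common = 1000)
}

#' Write a recording back to the CSV layout
#'
#' Inverse of [read_recording()]: one CSV per device with a header row of
#' channel labels, full double precision (round-trips exactly).
#'
#' @param rec A [bci_recording()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"001FN03.mat"`.
#' @return Invisibly, the named list of files written.
#' @export
write_recording <- function(rec, dir, prefix = "recording") {
  stopifnot(inherits(rec, "bci_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- list()
  put <- function(series, path) {
    df <- tibble::as_tibble(lapply(series, function(ts) ts$samples),
                            .name_repair = "minimal")
    names(df) <- vapply(series, function(ts) ts$label, character(1))
    readr::write_csv(df, path, progress = FALSE)
    path
  }
  if (length(rec$eeg) > 0) {
    written$eeg <- put(rec$eeg, file.path(dir, paste0(prefix, "_EEG.csv")))
  }
  for (muscle in names(rec$emg)) {
    if (length(rec$emg[[muscle]]) == 0) next
    written[[paste0("emg.", muscle)]] <-
      put(rec$emg[[muscle]],
          file.path(dir, paste0(prefix, "_sEMG.", muscle, ".csv")))
  }
  for (sensor in names(rec$imu)) {
    written[[paste0("imu.", sensor)]] <-
      put(rec$imu[[sensor]],
          file.path(dir, paste0(prefix, "_IMU.", sensor, ".csv")))
  }
  invisible(written)
}
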