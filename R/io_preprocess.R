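#' @keywords internal
"_PACKAGE"

SENSOR_LOCATIONS <- c("torso", "wrist_left", "wrist_right",
                      "ankle_left", "ankle_right")
PHASE_NAMES <- c("Play", "SF1", "R1", "SF2", "R2")

#' Construct a tri-axial free-acceleration recording
#'
#' Container for one wearable sensor's gravity-subtracted (free)
#' acceleration during a still-face paradigm session, together with the
#' annotated phase boundaries (Play, SF1, R1, SF2, R2; the A-B-A-B-A
#' design). Phase intervals are half-open `[start, end)` in 0-based sample
#' indices.
#'
#' @param t monotone time vector in seconds.
#' @param xyz numeric matrix, one column per axis (x, y, z), in m/s^2.
#' @param fs sampling rate in Hz.
#' @param phase_marks named list of `c(start_index, end_index)` 0-based
#'   half-open intervals, names among `Play, SF1, R1, SF2, R2`, in order.
#' @param sensor_location one of torso, wrist_left, wrist_right,
#'   ankle_left, ankle_right.
#' @param participant,group optional metadata labels.
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(t, xyz, fs = 100, phase_marks = list(),
                            sensor_location = "torso",
                            participant = NA_character_,
                            group = NA_character_) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have exactly 3 columns")
  if (nrow(xyz) != length(t)) stop("time vector and axes differ in length")
  if (fs <= 0) stop("fs must be positive")
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("time column must be strictly increasing")
  }
  sensor_location <- match.arg(sensor_location, SENSOR_LOCATIONS)
  validate_phase_marks(phase_marks, nrow(xyz))
  structure(
    list(t = as.numeric(t), xyz = unname(xyz), fs = fs,
         phase_marks = phase_marks, sensor_location = sensor_location,
         participant = participant, group = group),
    class = "accel_recording"
  )
}

validate_phase_marks <- function(phase_marks, n) {
  if (length(phase_marks) == 0) return(invisible(TRUE))
  bad <- setdiff(names(phase_marks), PHASE_NAMES)
  if (length(bad) > 0) stop("unknown phase name(s): ", paste(bad, collapse = ", "))
  ord <- match(names(phase_marks), PHASE_NAMES)
  if (is.unsorted(ord, strictly = TRUE)) {
    stop("phases must appear in Play, SF1, R1, SF2, R2 order")
  }
  prev_end <- -1
  for (nm in names(phase_marks)) {
    iv <- phase_marks[[nm]]
    if (length(iv) != 2 || iv[1] < 0 || iv[2] <= iv[1] || iv[2] > n) {
      stop("invalid interval for phase ", nm)
    }
    if (iv[1] < prev_end) stop("phase intervals overlap at ", nm)
    prev_end <- iv[2]
  }
  invisible(TRUE)
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %s, %d samples @ %g Hz, %d phase(s)\n",
              x$sensor_location, nrow(x$xyz), x$fs, length(x$phase_marks)))
  invisible(x)
}

#' Read a sensor recording from delimited text
#'
#' Expects columns `time_s, acc_x, acc_y, acc_z` (header required; comma or
#' tab separated). Phase annotations come from a sidecar table with columns
#' `phase, start_s` and optional `duration_s` (default 120 s per phase,
#' matching the 2-min still-face phases).
#'
#' @param path path to the recording file.
#' @param fs sampling rate in Hz (default 100).
#' @param phase_table path to the phase table CSV, or a data.frame.
#' @param sensor_location,participant,group metadata (see
#'   [accel_recording()]).
#' @return an `accel_recording`.
#' @export
read_recording <- function(path, fs = 100, phase_table = NULL,
                           sensor_location = "torso",
                           participant = NA_character_,
                           group = NA_character_) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  need <- c("time_s", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[, need]))
  if (length(bad) > 0) {
    stop("malformed/missing values at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  marks <- list()
  if (!is.null(phase_table)) {
    pt <- if (is.data.frame(phase_table)) phase_table else
      utils::read.csv(phase_table)
    if (is.null(pt$duration_s)) pt$duration_s <- 120
    marks <- phase_marks_from_times(pt, df$time_s, fs)
  }
  accel_recording(df$time_s, as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                  fs = fs, phase_marks = marks,
                  sensor_location = sensor_location,
                  participant = participant, group = group)
}

# convert (phase, start_s, duration_s) rows to 0-based half-open sample
# intervals on the recording's time base
phase_marks_from_times <- function(pt, t, fs) {
  pt <- pt[order(match(pt$phase, PHASE_NAMES)), ]
  n <- length(t)
  t0 <- t[1]
  marks <- list()
  for (i in seq_len(nrow(pt))) {
    start <- round((pt$start_s[i] - t0) * fs)
    end <- min(start + round(pt$duration_s[i] * fs), n)
    if (start >= n) next
    marks[[as.character(pt$phase[i])]] <- c(max(start, 0), end)
  }
  marks
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]; used for round-tripping synthetic data
#' through the text interface.
#'
#' @param rec an `accel_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$t, acc_x = rec$xyz[, 1],
                   acc_y = rec$xyz[, 2], acc_z = rec$xyz[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Low-pass filter a recording (20 Hz Butterworth, zero phase)
#'
#' Each axis is filtered identically with a Butterworth low-pass applied
#' forward-backward (zero phase distortion), prior to the magnitude step.
#' The 20 Hz default retains the spectral content of human movement while
#' removing high-frequency noise. Order defaults to 4; both are
#' configurable.
#'
#' @param rec an `accel_recording`.
#' @param cutoff cutoff frequency in Hz (default 20).
#' @param order filter order (default 4).
#' @return a filtered `accel_recording` of identical shape.
#' @export
lowpass_filter <- function(rec, cutoff = 20, order = 4) {
  if (cutoff >= rec$fs / 2) {
    stop("cutoff must be below the Nyquist frequency fs/2 = ", rec$fs / 2)
  }
  ba <- butter_design(order, cutoff, rec$fs, type = "low")
  out <- rec
  for (j in 1:3) out$xyz[, j] <- filtfilt_ba(ba$b, ba$a, rec$xyz[, j])
  out
}

#' Acceleration magnitude
#'
#' Per-sample Euclidean norm of the tri-axial free acceleration, the
#' "vector sum ... at each time point". Nonnegative by construction.
#'
#' @param rec an `accel_recording` (normally already low-pass filtered).
#' @return numeric vector of magnitudes in m/s^2.
#' @export
acceleration_magnitude <- function(rec) {
  sqrt(rowSums(rec$xyz^2))
}

#' Segment an acceleration-magnitude series into still-face phases
#'
#' Cuts the magnitude series at the annotated phase boundaries. A complete
#' 2-min phase at 100 Hz yields 12,000 samples; phases shorter than
#' `min_duration_s` are flagged incomplete (and should be excluded from
#' entropy analysis).
#'
#' @param mag magnitude series (from [acceleration_magnitude()]).
#' @param rec the `accel_recording` carrying `phase_marks` and `fs`.
#' @param min_duration_s minimum complete-phase duration (default 120 s).
#' @return list of `magnitude_phase` objects (fields: `phase`, `values`,
#'   `fs`, `n`, `complete`).
#' @export
segment_phases <- function(mag, rec, min_duration_s = 120) {
  if (length(rec$phase_marks) == 0) stop("recording has no phase annotations")
  n_min <- round(min_duration_s * rec$fs)
  out <- list()
  for (nm in names(rec$phase_marks)) {
    iv <- rec$phase_marks[[nm]]
    values <- mag[(iv[1] + 1):iv[2]]
    complete <- length(values) >= n_min
    if (!complete) {
      warning("phase ", nm, " incomplete (", length(values), " < ", n_min,
              " samples); excluded from entropy analysis", call. = FALSE)
    }
    out[[nm]] <- structure(
      list(phase = nm, values = values, fs = rec$fs, n = length(values),
           complete = complete),
      class = "magnitude_phase"
    )
  }
  out
}

#' @export
print.magnitude_phase <- function(x, ...) {
  cat(sprintf("<magnitude_phase> %s: %d samples @ %g Hz%s\n", x$phase, x$n,
              x$fs, if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' Outlier-trimmed mean acceleration magnitude
#'
#' Mean of the phase's acceleration magnitude after excluding samples
#' outside the two-sided Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' (quartiles by linear interpolation, `stats::quantile` type 7). For
#' nonnegative magnitudes the lower fence is usually vacuous.
#'
#' @param phase a `magnitude_phase`, or a bare numeric vector.
#' @return list with `mean` (m/s^2) and `n_excluded`.
#' @export
trimmed_mean_acceleration <- function(phase) {
  values <- if (inherits(phase, "magnitude_phase")) phase$values else phase
  if (length(values) < 4) stop("need at least 4 samples")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  list(mean = mean(values[keep]), n_excluded = sum(!keep))
}
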