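# End-to-end orchestration: filter -> magnitude -> segment -> trimmed
# mean + improved MPE + complexity indices for the motor level, and
# chromatic RQA for the behavioural level. Emits tidy tables (one row per
# participant/sensor/phase/measure) for any external statistics package;
# mixed-model inference is deliberately out of scope.

#' Pipeline run configuration
#'
#' Validated parameter bundle; every output row carries this parameter
#' fingerprint so each numeric cell is traceable to one operation
#' invocation.
#'
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @param filter_order Butterworth order.
#' @param m,lag,max_scale permutation-entropy parameters.
#' @param combine improved-MPE combination rule (`"mean"` or `"pooled"`).
#' @param bands band definitions (default [default_bands()]).
#' @param rounding frequency-to-scale rounding rule.
#' @param v_min minimum laminar length in samples.
#' @param loi_excluded exclude the line of identity.
#' @param min_duration_s minimum complete phase duration in seconds.
#' @param seed integer seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(fs = 100, cutoff = 20, filter_order = 4, m = 4,
                       lag = 1, max_scale = 50, combine = "mean",
                       bands = default_bands(), rounding = "half_up",
                       v_min = 3, loi_excluded = TRUE,
                       min_duration_s = 120, seed = 1L) {
  stopifnot(fs > 0, cutoff > 0, cutoff < fs / 2, filter_order >= 1,
            m >= 2, lag >= 1, max_scale >= 1, v_min >= 1)
  structure(list(fs = fs, cutoff = cutoff, filter_order = filter_order,
                 m = m, lag = lag, max_scale = max_scale, combine = combine,
                 bands = bands, rounding = rounding, v_min = v_min,
                 loi_excluded = loi_excluded,
                 min_duration_s = min_duration_s, seed = as.integer(seed)),
            class = "run_config")
}

fingerprint <- function(cfg) {
  sprintf("m=%d;lag=%d;scales=%d;combine=%s;cutoff=%g;order=%d;round=%s;vmin=%d;loi=%s",
          cfg$m, cfg$lag, cfg$max_scale, cfg$combine, cfg$cutoff,
          cfg$filter_order, cfg$rounding, cfg$v_min,
          if (cfg$loi_excluded) "excl" else "incl")
}

#' Run the motor (accelerometer) pipeline
#'
#' For every recording: low-pass filter, acceleration magnitude, phase
#' segmentation, then per complete phase the outlier-trimmed mean
#' acceleration, the 50-scale improved-MPE curve, the overall complexity
#' index and the five band complexity indices. Incomplete phases and
#' per-recording failures are logged and skipped; the run continues.
#'
#' @param recordings list of `accel_recording` objects (e.g. from
#'   [gen_cohort()] or [read_recording()]).
#' @param cfg a [run_config()].
#' @return list of class `motor_result` with tidy data.frames
#'   `acceleration` (participant, group, sensor, phase, mean_acc,
#'   n_excluded), `mse` (…, scale, pe, n_eff), `ci` (…, band, scale_low,
#'   scale_high, ci), and a character vector `log`.
#' @export
run_motor_pipeline <- function(recordings, cfg = run_config()) {
  if (inherits(recordings, "accel_recording")) recordings <- list(recordings)
  acc_rows <- list(); mse_rows <- list(); ci_rows <- list(); log <- character(0)
  fp <- fingerprint(cfg)
  for (rec in recordings) {
    res <- tryCatch({
      filt <- lowpass_filter(rec, cutoff = cfg$cutoff,
                             order = cfg$filter_order)
      mag <- acceleration_magnitude(filt)
      withCallingHandlers(
        segment_phases(mag, rec, min_duration_s = cfg$min_duration_s),
        warning = function(w) {
          log <<- c(log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) {
      log <<- c(log, sprintf("recording %s/%s failed: %s", rec$participant,
                             rec$sensor_location, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    for (ph in res) {
      tm <- trimmed_mean_acceleration(ph)
      acc_rows[[length(acc_rows) + 1]] <- data.frame(
        participant = rec$participant, group = rec$group,
        sensor = rec$sensor_location, phase = ph$phase,
        mean_acc = tm$mean, n_excluded = tm$n_excluded,
        complete = ph$complete, params = fp)
      if (!ph$complete) next
      curve <- improved_mpe(ph$values, m = cfg$m, lag = cfg$lag,
                            max_scale = cfg$max_scale,
                            combine = cfg$combine,
                            meta = list(participant = rec$participant,
                                        sensor = rec$sensor_location,
                                        phase = ph$phase))
      mse_rows[[length(mse_rows) + 1]] <- data.frame(
        participant = rec$participant, group = rec$group,
        sensor = rec$sensor_location, phase = ph$phase,
        scale = curve$scale, pe = curve$pe, n_eff = curve$n_eff,
        params = fp)
      overall <- complexity_index(curve)
      btab <- band_table(curve, bands = cfg$bands, fs = cfg$fs,
                         max_scale = cfg$max_scale, rounding = cfg$rounding)
      ci_rows[[length(ci_rows) + 1]] <- rbind(
        data.frame(participant = rec$participant, group = rec$group,
                   sensor = rec$sensor_location, phase = ph$phase,
                   band = "overall", scale_low = overall$scales_used[1],
                   scale_high = overall$scales_used[2],
                   ci = overall$value, params = fp),
        data.frame(participant = rec$participant, group = rec$group,
                   sensor = btab$sensor, phase = btab$phase,
                   band = btab$band, scale_low = btab$scale_low,
                   scale_high = btab$scale_high, ci = btab$ci, params = fp))
    }
  }
  structure(list(acceleration = do.call(rbind, acc_rows),
                 mse = do.call(rbind, mse_rows),
                 ci = do.call(rbind, ci_rows), log = log),
            class = "motor_result")
}

#' Run the behavioural (chromatic RQA) pipeline
#'
#' One row of RR, LAM, TT and ENTb per participant and phase, plus the
#' total ER occupancy as a proportion of the phase. Sequences departing
#' from the expected length are excluded with a logged reason; missing
#' phases are tolerated (fewer observations than 2N is legal).
#'
#' @param codes data.frame with columns `participant, phase, t_s, state`
#'   (one row per second), or a path to such a CSV; alternatively a list
#'   of `behaviour_sequence` objects.
#' @param cfg a [run_config()].
#' @param expected_T required sequence length (default 120); tolerance 0.
#' @return list of class `behaviour_result` with data.frame `measures`
#'   (participant, group, phase, rr, lam, tt, entb, er_prop, v_min,
#'   loi_excluded, params) and `log`.
#' @export
run_behaviour_pipeline <- function(codes, cfg = run_config(),
                                   expected_T = 120) {
  seqs <- list()
  if (is.character(codes)) codes <- utils::read.csv(codes)
  if (is.data.frame(codes)) {
    if (nrow(codes) == 0) stop("empty behaviour input")
    need <- c("participant", "phase", "t_s", "state")
    if (!all(need %in% names(codes))) {
      stop("missing column(s): ",
           paste(setdiff(need, names(codes)), collapse = ", "))
    }
    for (key in unique(paste(codes$participant, codes$phase, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- codes[codes$participant == parts[1] & codes$phase == parts[2], ]
      sub <- sub[order(sub$t_s), ]
      grp <- if (!is.null(sub$group)) sub$group[1] else NA_character_
      seqs[[length(seqs) + 1]] <- behaviour_sequence(
        sub$state, phase = parts[2], participant = parts[1], group = grp)
    }
  } else {
    seqs <- codes
  }
  rows <- list(); log <- character(0)
  fp <- fingerprint(cfg)
  for (sq in seqs) {
    if (length(sq$states) != expected_T) {
      log <- c(log, sprintf("%s/%s excluded: length %d != %d",
                            sq$participant, sq$phase, length(sq$states),
                            expected_T))
      next
    }
    m <- rqa_measures(sq, v_min = cfg$v_min,
                      loi_excluded = cfg$loi_excluded)
    rows[[length(rows) + 1]] <- data.frame(
      participant = sq$participant, group = sq$group, phase = sq$phase,
      rr = m$rr, lam = m$lam, tt = m$tt, entb = m$entb,
      er_prop = mean(sq$states %in% ER_STATES),
      v_min = m$v_min, loi_excluded = m$loi_excluded, params = fp)
  }
  structure(list(measures = do.call(rbind, rows), log = log),
            class = "behaviour_result")
}
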