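# Synthetic stand-in for the restricted cohort data: band-structured
# accelerometer noise with controllable per-band, per-phase and per-group
# effects, and categorical behaviour sequences with controllable state
# occupancy and bout-length distributions. A statistical emulation of the
# design, not a biomechanical simulation.

# deterministic sub-seed from a base seed and a string key (kept < 2^31)
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Scenario for synthetic accelerometer signals
#'
#' Defaults describe resting/playing infant movement with spectral power
#' concentrated at low frequencies: per-band noise amplitudes (m/s^2,
#' standard deviation of the band-limited component per axis) decay from
#' delta to gamma, plus a small white measurement-noise floor. Phase and
#' group effects are multiplicative modulations of band amplitude and
#' default to 1 (no effect); tests inject effects explicitly.
#'
#' @param fs sampling rate in Hz (default 100).
#' @param duration_s phase duration in seconds (default 120).
#' @param band_amplitudes named vector, amplitude per band in m/s^2.
#' @param phase_effects named list: phase -> named multiplier vector per
#'   band (missing entries mean 1).
#' @param group_effects named list: group -> list(sensor -> named
#'   multiplier vector per band) (missing entries mean 1).
#' @param measurement_noise_sd white-noise floor in m/s^2.
#' @param seed base integer seed; all randomness derives from it.
#' @return list of class `signal_scenario`.
#' @export
signal_scenario <- function(fs = 100, duration_s = 120,
                            band_amplitudes = c(gamma = 0.1, beta = 0.2,
                                                alpha = 0.35, theta = 0.5,
                                                delta = 0.8),
                            phase_effects = list(),
                            group_effects = list(),
                            measurement_noise_sd = 0.05,
                            seed = 1L) {
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs must be integral")
  structure(list(fs = fs, duration_s = duration_s,
                 band_amplitudes = band_amplitudes,
                 phase_effects = phase_effects,
                 group_effects = group_effects,
                 measurement_noise_sd = measurement_noise_sd,
                 seed = as.integer(seed)),
            class = "signal_scenario")
}

# unit-variance Gaussian noise band-limited to [f_low, f_high] by
# brick-wall FFT masking (exact band edges, no filter transition band)
band_limited_noise <- function(n, fs, f_low, f_high) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f_alias <- pmin(f, fs - f)
  mask <- f_alias >= f_low & f_alias <= f_high
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

band_multiplier <- function(effects, band) {
  if (is.null(effects) || !(band %in% names(effects))) return(1)
  as.numeric(effects[[band]])
}

#' Generate one synthetic acceleration phase
#'
#' Each axis is a sum over the five frequency bands of band-limited
#' Gaussian noise scaled by `amplitude x phase_effect x group_effect`,
#' plus white measurement noise. Bit-reproducible given
#' `(scenario seed, group, phase, sensor, participant)`.
#'
#' @param scn a [signal_scenario()].
#' @param group,phase,sensor,participant labels keying the deterministic
#'   sub-seed and selecting the applicable effects.
#' @param bands band definitions (default [default_bands()]).
#' @return list with `t` (seconds) and `xyz` (n x 3 matrix, m/s^2).
#' @export
gen_accel_phase <- function(scn, group = "term", phase = "Play",
                            sensor = "torso", participant = "p1",
                            bands = default_bands()) {
  n <- as.integer(round(scn$duration_s * scn$fs))
  key <- paste(group, phase, sensor, participant, sep = "|")
  set.seed(derive_seed(scn$seed, key))
  xyz <- matrix(0, n, 3)
  pe <- scn$phase_effects[[phase]]
  ge <- scn$group_effects[[group]][[sensor]]
  for (ax in 1:3) {
    sig <- numeric(n)
    for (i in seq_len(nrow(bands))) {
      bn <- bands$band[i]
      amp <- scn$band_amplitudes[[bn]]
      amp <- amp * band_multiplier(pe, bn) * band_multiplier(ge, bn)
      if (amp > 0) {
        sig <- sig + amp * band_limited_noise(n, scn$fs, bands$f_low[i],
                                              bands$f_high[i])
      }
    }
    if (scn$measurement_noise_sd > 0) {
      sig <- sig + stats::rnorm(n, sd = scn$measurement_noise_sd)
    }
    xyz[, ax] <- sig
  }
  list(t = (seq_len(n) - 1) / scn$fs, xyz = xyz)
}

#' Generate a synthetic still-face cohort
#'
#' Full A-B-A-B-A (Play, SF1, R1, SF2, R2) recordings for `n_term` term
#' and `n_preterm` preterm participants at all five sensor locations, with
#' the scenario's group and phase effects applied. Deterministic per
#' (participant, sensor, scenario seed).
#'
#' @param n_term,n_preterm participants per group (>= 1).
#' @param scn a [signal_scenario()].
#' @param sensors sensor locations to simulate (default all five).
#' @return list of `accel_recording` objects with participant/group
#'   metadata and complete phase annotations.
#' @export
gen_cohort <- function(n_term, n_preterm, scn,
                       sensors = SENSOR_LOCATIONS) {
  if (n_term < 1 || n_preterm < 1) stop("need at least one participant per group")
  ids <- c(sprintf("term_%02d", seq_len(n_term)),
           sprintf("preterm_%02d", seq_len(n_preterm)))
  groups <- rep(c("term", "preterm"), c(n_term, n_preterm))
  n_phase <- as.integer(round(scn$duration_s * scn$fs))
  out <- list()
  for (i in seq_along(ids)) {
    for (sensor in sensors) {
      xyz <- matrix(0, 0, 3)
      marks <- list()
      for (k in seq_along(PHASE_NAMES)) {
        ph <- gen_accel_phase(scn, group = groups[i], phase = PHASE_NAMES[k],
                              sensor = sensor, participant = ids[i])
        marks[[PHASE_NAMES[k]]] <- c((k - 1) * n_phase, k * n_phase)
        xyz <- rbind(xyz, ph$xyz)
      }
      t <- (seq_len(nrow(xyz)) - 1) / scn$fs
      out[[length(out) + 1]] <- accel_recording(
        t, xyz, fs = scn$fs, phase_marks = marks,
        sensor_location = sensor, participant = ids[i], group = groups[i])
    }
  }
  out
}

#' Scenario for synthetic behaviour sequences
#'
#' Defaults emulate still-face-phase self-regulation coding with uneven
#' state occupancy (one dominant distraction state) and geometric bout
#' lengths with a 4 s mean — consistent with cohort-level recurrence rates
#' near 20%, laminarity near 80% and trapping times near 4 s.
#'
#' @param T sequence length in samples (seconds; default 120).
#' @param state_probs named probability vector over the six states
#'   (five ER states + "none"); must sum to 1.
#' @param mean_bout_s expected bout duration in seconds (scalar, or named
#'   per state).
#' @param bout_dist `"geometric"` (default), `"fixed"` or `"lognormal"`.
#' @param sigma log-scale sd for the lognormal option (default 0.5).
#' @param seed base integer seed.
#' @return list of class `behaviour_scenario`.
#' @export
behaviour_scenario <- function(T = 120,
                               state_probs = c(oral_tactile = 0.10,
                                               object_distraction = 0.25,
                                               social_interactive = 0.10,
                                               motor_stimulatory = 0.10,
                                               distancing = 0.05,
                                               none = 0.40),
                               mean_bout_s = 4,
                               bout_dist = c("geometric", "fixed",
                                             "lognormal"),
                               sigma = 0.5, seed = 1L) {
  bout_dist <- match.arg(bout_dist)
  bad <- setdiff(names(state_probs), BEHAVIOUR_ALPHABET)
  if (length(bad) > 0) stop("unknown state(s): ", paste(bad, collapse = ", "))
  if (abs(sum(state_probs) - 1) > 1e-8) stop("state_probs must sum to 1")
  if (any(mean_bout_s < 1)) stop("mean_bout_s must be >= 1")
  structure(list(T = T, state_probs = state_probs,
                 mean_bout_s = mean_bout_s, bout_dist = bout_dist,
                 sigma = sigma, seed = as.integer(seed)),
            class = "behaviour_scenario")
}

# bout length from a uniform draw by inverse transform, so that for a
# fixed seed lengths are monotone in the mean (comparable across
# scenarios that differ only in mean bout length)
bout_length <- function(u, mean_s, dist, sigma) {
  switch(dist,
         fixed = max(1L, as.integer(round(mean_s))),
         geometric = 1L + stats::qgeom(u, prob = 1 / mean_s),
         lognormal = max(1L, as.integer(round(stats::qlnorm(
           u, meanlog = log(mean_s) - sigma^2 / 2, sdlog = sigma)))))
}

#' Generate a synthetic behaviour sequence
#'
#' Alternating-bout construction: draw a state from `state_probs`
#' (resampling so consecutive bouts differ, when possible), draw a bout
#' length from the bout distribution with that state's mean, append, and
#' repeat until `T` samples; the final bout is truncated.
#'
#' @param scn a [behaviour_scenario()].
#' @param phase,participant,group metadata, also keyed into the sub-seed.
#' @return a [behaviour_sequence()] of exactly `T` samples.
#' @export
gen_behaviour_sequence <- function(scn, phase = "SF1", participant = "p1",
                                   group = "term") {
  set.seed(derive_seed(scn$seed, paste(phase, participant, sep = "|")))
  probs <- scn$state_probs
  states_avail <- names(probs)
  seq_out <- character(0)
  prev <- NA_character_
  while (length(seq_out) < scn$T) {
    st <- sample(states_avail, 1, prob = probs)
    if (!is.na(prev) && st == prev && sum(probs > 0) > 1) next
    mean_s <- if (length(scn$mean_bout_s) > 1) scn$mean_bout_s[[st]]
              else scn$mean_bout_s
    len <- bout_length(stats::runif(1), mean_s, scn$bout_dist, scn$sigma)
    seq_out <- c(seq_out, rep(st, len))
    prev <- st
  }
  behaviour_sequence(seq_out[seq_len(scn$T)], phase = phase,
                     participant = participant, group = group)
}
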