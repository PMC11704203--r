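# Complexity index (area under the multiscale-entropy curve) and its
# reduction onto EEG-style frequency bands via the scale <-> frequency map
# scale = fs / f (anchor: scale 50 at fs = 100 Hz examines activity at
# 2 Hz, i.e. a 0.5 s inter-sample interval).

#' Default frequency-band definitions
#'
#' The five EEG-convention bands used to map the multiscale entropy curve
#' onto frequency ranges: gamma 30-45 Hz, beta 14-30 Hz, alpha 8-13.5 Hz,
#' theta 4.5-7.5 Hz, delta 0.5-4 Hz. Higher-frequency bands correspond to
#' smaller scale factors.
#'
#' @return data.frame with columns `band`, `f_low`, `f_high` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    band = c("gamma", "beta", "alpha", "theta", "delta"),
    f_low = c(30, 14, 8, 4.5, 0.5),
    f_high = c(45, 30, 13.5, 7.5, 4)
  )
}

#' Scale factor examining a given frequency
#'
#' Coarse-graining at scale `s` examines activity at `fs / s` Hz, so the
#' scale for frequency `f` is `fs / f`, rounded (half away from zero by
#' default) and clamped to `[1, max_scale]`. The delta-band lower edge
#' (0.5 Hz at fs = 100) would need scale 200 and is clamped to 50.
#'
#' @param f frequency in Hz (`0 < f <= fs/2` before clamping is sensible,
#'   but any positive f is accepted and clamped).
#' @param fs sampling rate in Hz.
#' @param max_scale highest available scale factor (default 50).
#' @param rounding `"half_up"` (default), `"floor"` or `"ceiling"`.
#' @return integer scale factor in `[1, max_scale]`.
#' @export
scale_for_frequency <- function(f, fs, max_scale = 50,
                                rounding = c("half_up", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (any(f <= 0)) stop("frequency must be positive")
  raw <- fs / f
  s <- switch(rounding,
              half_up = floor(raw + 0.5),
              floor = floor(raw),
              ceiling = ceiling(raw))
  as.integer(pmin(pmax(s, 1), max_scale))
}

#' Scale-factor range of a frequency band
#'
#' The band's high-frequency edge maps to the smallest scale and its
#' low-frequency edge to the largest; the range is inclusive.
#'
#' @param f_low,f_high band edges in Hz (`f_high > f_low > 0`).
#' @param fs sampling rate in Hz.
#' @param max_scale highest available scale factor.
#' @param rounding passed to [scale_for_frequency()].
#' @return integer vector `c(scale_low, scale_high)`.
#' @export
band_scale_range <- function(f_low, f_high, fs, max_scale = 50,
                             rounding = "half_up") {
  if (f_high <= f_low || f_low <= 0) stop("need f_high > f_low > 0")
  lo <- scale_for_frequency(f_high, fs, max_scale, rounding)
  hi <- scale_for_frequency(f_low, fs, max_scale, rounding)
  if (lo > hi) stop("band [", f_low, ", ", f_high,
                    "] Hz maps to an empty scale range after clamping")
  c(lo, hi)
}

#' Complexity index: area under the multiscale-entropy curve
#'
#' Sum of normalized permutation entropy over an inclusive range of scale
#' factors. The overall complexity index uses all 50 scales; band-specific
#' indices sum only the scales mapped to a named frequency band.
#'
#' @param curve an `mse_curve` from [improved_mpe()].
#' @param scale_low,scale_high inclusive scale range (defaults: full
#'   curve).
#' @param band optional band label stored on the result.
#' @return list of class `complexity_index` with `value`, `scales_used`
#'   and `band`.
#' @export
complexity_index <- function(curve, scale_low = min(curve$scale),
                             scale_high = max(curve$scale),
                             band = "overall") {
  wanted <- scale_low:scale_high
  missing <- setdiff(wanted, curve$scale)
  if (length(missing) > 0) {
    stop("scale(s) missing from curve: ", paste(missing, collapse = ", "))
  }
  structure(
    list(value = sum(curve$pe[curve$scale %in% wanted]),
         scales_used = c(scale_low, scale_high), band = band),
    class = "complexity_index"
  )
}

#' @export
print.complexity_index <- function(x, ...) {
  cat(sprintf("<complexity_index> %s [scales %d-%d]: %.4f\n", x$band,
              x$scales_used[1], x$scales_used[2], x$value))
  invisible(x)
}

#' Band-specific complexity indices for a set of MSE curves
#'
#' One row per curve and band, with the realized (post-rounding,
#' post-clamping) scale range made explicit so band definitions are
#' auditable.
#'
#' @param curves a single `mse_curve` or a list of them (each carrying
#'   `meta` labels).
#' @param bands band definition data.frame (default [default_bands()]).
#' @param fs sampling rate in Hz.
#' @param max_scale highest scale factor (default 50).
#' @param rounding passed to [scale_for_frequency()].
#' @return tidy data.frame: participant, sensor, phase, band, scale_low,
#'   scale_high, ci.
#' @export
band_table <- function(curves, bands = default_bands(), fs = 100,
                       max_scale = 50, rounding = "half_up") {
  if (inherits(curves, "mse_curve")) curves <- list(curves)
  rows <- list()
  for (curve in curves) {
    meta <- attr(curve, "meta")
    lab <- function(k) if (is.null(meta[[k]])) NA_character_ else meta[[k]]
    for (i in seq_len(nrow(bands))) {
      rng <- band_scale_range(bands$f_low[i], bands$f_high[i], fs,
                              max_scale, rounding)
      ci <- complexity_index(curve, rng[1], rng[2], band = bands$band[i])
      rows[[length(rows) + 1]] <- data.frame(
        participant = lab("participant"), sensor = lab("sensor"),
        phase = lab("phase"), band = bands$band[i],
        scale_low = rng[1], scale_high = rng[2], ci = ci$value
      )
    }
  }
  do.call(rbind, rows)
}

#' Distinct band-edge scale factors
#'
#' The scale factors obtained by mapping every band edge through
#' [scale_for_frequency()], deduplicated and sorted. Used for the
#' MSE-curve-profile analysis, which reduces the 50-scale curve to the
#' edge scales only (realized as a filter on the tidy entropy table).
#'
#' @inheritParams band_table
#' @return sorted integer vector of distinct edge scale factors.
#' @export
edge_scales <- function(bands = default_bands(), fs = 100, max_scale = 50,
                        rounding = "half_up") {
  s <- scale_for_frequency(c(bands$f_low, bands$f_high), fs, max_scale,
                           rounding)
  sort(unique(s))
}
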