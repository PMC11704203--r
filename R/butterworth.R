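#' Butterworth filter design (digital, via bilinear transform)
#'
#' Designs the transfer-function coefficients of a digital Butterworth
#' low-pass or band-pass filter. Implemented in base R (poles of the analog
#' prototype, frequency pre-warping, bilinear transform) because ordinal
#' pattern analysis is sensitive to phase distortion and we need full
#' control over the zero-phase application in [filtfilt()].
#'
#' @param order filter order (of the low-pass prototype; a band-pass of
#'   order `n` has `2n` poles).
#' @param cutoff cutoff frequency in Hz (length 1 for `"low"`, length 2
#'   `c(low, high)` for `"pass"`).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @keywords internal
butter_design <- function(order, cutoff, fs, type = c("low", "pass")) {
  type <- match.arg(type)
  if (order < 1) stop("filter order must be >= 1")
  if (any(cutoff <= 0) || any(cutoff >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k - 1) / (2 * order) + 1i * pi / 2)
  fs2 <- 2 * fs
  if (type == "low") {
    warped <- fs2 * tan(pi * cutoff / fs)
    p <- p * warped
    z <- complex(0)
    gain <- warped^order
  } else {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2]) {
      stop("band-pass requires cutoff = c(low, high) with low < high")
    }
    w1 <- fs2 * tan(pi * cutoff[1] / fs)
    w2 <- fs2 * tan(pi * cutoff[2] / fs)
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    # low-pass -> band-pass pole transformation
    p_lp <- p * bw / 2
    p <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
    z <- rep(0 + 0i, order)
    gain <- bw^order
  }
  # bilinear transform s -> fs2 (z-1)/(z+1)
  pz <- (1 + p / fs2) / (1 - p / fs2)
  zz <- (1 + z / fs2) / (1 - z / fs2)
  # zeros at infinity map to z = -1
  zz <- c(zz, rep(-1 + 0i, length(p) - length(z)))
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  b <- Re(poly_from_roots(zz)) * gain
  a <- Re(poly_from_roots(pz))
  list(b = b / a[1], a = a / a[1])
}

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - ri * c(0, coef)
  coef
}

# single-pass IIR filter y = filter(b, a, x); recursion done in C via
# stats::filter, convolution part likewise
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + n)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice, forwards then backwards, cancelling the phase
#' response; the effective magnitude response is squared. Edge transients
#' are controlled by odd-reflection padding at both ends, as is standard in
#' biomechanical signal processing.
#'
#' @param b,a transfer-function coefficients from [butter_design()].
#' @param x numeric series.
#' @return filtered series, same length as `x`.
#' @keywords internal
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  # pad long enough for the zero-state startup transient to decay below
  # ~1e-13: the transient shrinks by the largest pole modulus per sample
  rmax <- if (length(a) > 1) max(Mod(polyroot(rev(a)))) else 0
  decay <- if (rmax > 0 && rmax < 1) ceiling(log(1e-13) / log(rmax)) else n - 1
  npad <- min(max(3 * max(length(a), length(b)), decay), n - 1)
  if (npad > 0) {
    head_pad <- 2 * x[1] - x[(npad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Analytic magnitude response of a digital Butterworth low-pass
#'
#' Closed form for the bilinear-transformed Butterworth low-pass:
#' `|H(f)| = 1 / sqrt(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))`.
#' Used to validate the filter implementation against theory.
#'
#' @param f frequency in Hz at which to evaluate the response.
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order.
#' @return magnitude gain in `[0, 1]`.
#' @export
butter_lowpass_gain <- function(f, cutoff, fs, order = 4) {
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / sqrt(1 + ratio^(2 * order))
}
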