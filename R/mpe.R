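# Ordinal-pattern permutation entropy and improved multiscale permutation
# entropy (IMPE). Defaults m = 4, lag = 1, 50 scale factors.

# Lexicographic rank (0-based) of the ordinal pattern of each embedding
# window. Ties broken by temporal order (stable sort): a later equal value
# counts as larger, so the Lehmer digit for position j is the number of
# strictly smaller values occurring later in the window.
ordinal_codes <- function(x, m, lag = 1) {
  nw <- length(x) - (m - 1) * lag
  if (nw < 1) stop("series shorter than one embedding window")
  idx <- seq_len(nw)
  W <- matrix(0, nw, m)
  for (j in seq_len(m)) W[, j] <- x[idx + (j - 1) * lag]
  fact <- factorial((m - 1):0)
  code <- numeric(nw)
  for (j in seq_len(m - 1)) {
    d <- 0
    for (k in (j + 1):m) d <- d + (W[, k] < W[, j])
    code <- code + d * fact[j]
  }
  as.integer(code)
}

#' Ordinal pattern index of a single window
#'
#' Returns the lexicographic rank in `[0, m! - 1]` of the permutation that
#' sorts the window ascending, with ties broken by temporal order (the
#' standard Bandt-Pompe convention). A strictly increasing window maps to
#' 0; a strictly decreasing window to `m! - 1`.
#'
#' @param window numeric vector of exactly `m` values.
#' @param m embedding dimension (defaults to the window length).
#' @return integer pattern index.
#' @export
ordinal_pattern <- function(window, m = length(window)) {
  if (m < 2) stop("embedding dimension m must be >= 2")
  if (length(window) != m) stop("window must contain exactly m values")
  ordinal_codes(window, m, lag = 1)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution over all embedding
#' windows, normalized by `log(m!)` so that 0 means perfectly regular
#' (a single pattern, e.g. a monotone series) and 1 means all `m!` patterns
#' equally frequent (the white-noise limit).
#'
#' @param x numeric series.
#' @param m embedding dimension (default 4).
#' @param lag embedding delay in samples (default 1).
#' @param normalize divide by `log(m!)` (default TRUE).
#' @return entropy in `[0, 1]` when normalized, else in nats.
#' @export
permutation_entropy <- function(x, m = 4, lag = 1, normalize = TRUE) {
  if (m < 2) stop("embedding dimension m must be >= 2")
  if (lag < 1) stop("lag must be >= 1")
  nw <- length(x) - (m - 1) * lag
  if (nw < 1) stop("series too short for a single embedding window")
  if (nw < 5 * factorial(m)) {
    warning("fewer than 5 * m! windows (", nw, "); entropy estimate unstable",
            call. = FALSE)
  }
  codes <- ordinal_codes(x, m, lag)
  counts <- tabulate(codes + 1L, nbins = factorial(m))
  p <- counts[counts > 0] / nw
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

#' Coarse-grain a series at a given scale factor
#'
#' Replaces the series by means of consecutive non-overlapping windows of
#' length `scale`, starting at `offset` (0-based, `0 <= offset < scale`).
#' Coarse-graining at scale `s` exposes dynamics at frequency `fs / s`: a
#' 12,000-sample phase at scale 50 yields a 240-point series.
#'
#' @param x numeric series.
#' @param scale window length (scale factor), integer >= 1.
#' @param offset 0-based starting offset in `[0, scale - 1]`.
#' @return averaged series of length `floor((length(x) - offset) / scale)`.
#' @export
coarse_grain <- function(x, scale, offset = 0) {
  if (scale < 1) stop("scale must be >= 1")
  if (offset < 0 || offset >= scale) stop("offset must be in [0, scale - 1]")
  nk <- (length(x) - offset) %/% scale
  if (nk < 1) stop("series shorter than one coarse-graining window")
  y <- x[(offset + 1):(offset + nk * scale)]
  if (scale == 1) return(y)
  colMeans(matrix(y, nrow = scale))
}

#' Improved multiscale permutation entropy
#'
#' For each scale factor `s`, permutation entropy is computed on each of
#' the `s` offset-shifted coarse-grainings of the series, and the `s`
#' estimates are combined — by averaging the entropies (default) or by
#' pooling the pattern histograms before taking the entropy. Using all
#' offsets stabilizes the estimate for short coarse-grained series (at
#' scale 50 a 12,000-sample phase leaves only 240 points per offset).
#' Scale 1 equals plain [permutation_entropy()].
#'
#' @param x numeric series.
#' @param m,lag see [permutation_entropy()].
#' @param max_scale highest scale factor (default 50).
#' @param scales scale factors to evaluate (default `1:max_scale`).
#' @param combine `"mean"` (average of per-offset entropies, default) or
#'   `"pooled"` (entropy of the pooled pattern histogram).
#' @param meta optional named list of labels (participant, sensor, phase)
#'   attached to the result.
#' @return data.frame of class `mse_curve` with columns `scale`, `pe`,
#'   `n_eff` (`floor(N / s)`). Scales with too few samples are dropped with
#'   a warning.
#' @export
improved_mpe <- function(x, m = 4, lag = 1, max_scale = 50,
                         scales = seq_len(max_scale),
                         combine = c("mean", "pooled"), meta = list()) {
  combine <- match.arg(combine)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1)) stop("scale factors must be >= 1")
  n <- length(x)
  nfact <- factorial(m)
  pe <- rep(NA_real_, length(scales))
  min_len <- (m - 1) * lag + 1
  for (i in seq_along(scales)) {
    s <- scales[i]
    # offsets whose coarse-grained series still holds one embedding window
    offsets <- (0:(s - 1))[((n - 0:(s - 1)) %/% s) >= min_len]
    if (length(offsets) == 0) next
    if (combine == "mean") {
      vals <- vapply(offsets, function(o) {
        suppressWarnings(permutation_entropy(coarse_grain(x, s, o), m, lag))
      }, 0)
      pe[i] <- mean(vals)
    } else {
      counts <- numeric(nfact)
      for (o in offsets) {
        codes <- ordinal_codes(coarse_grain(x, s, o), m, lag)
        counts <- counts + tabulate(codes + 1L, nbins = nfact)
      }
      p <- counts[counts > 0] / sum(counts)
      pe[i] <- -sum(p * log(p)) / log(nfact)
    }
  }
  if (anyNA(pe)) {
    warning("curve truncated: series too short at scale(s) ",
            paste(scales[is.na(pe)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(scale = scales[!is.na(pe)], pe = pe[!is.na(pe)],
                    n_eff = n %/% scales[!is.na(pe)])
  attr(out, "params") <- list(m = m, lag = lag, max_scale = max_scale,
                              combine = combine)
  attr(out, "meta") <- meta
  class(out) <- c("mse_curve", "data.frame")
  out
}
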