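# Independent brute-force oracles. These deliberately share no code with
# the package internals: dictionary counting over explicit windows for
# permutation entropy, and naive full-matrix scans for RQA.

brute_pe <- function(x, m = 4, lag = 1, normalize = TRUE) {
  nw <- length(x) - (m - 1) * lag
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nw)) {
    w <- x[i + (0:(m - 1)) * lag]
    key <- paste(order(w), collapse = "-")
    prev <- if (is.null(counts[[key]])) 0 else counts[[key]]
    counts[[key]] <- prev + 1
  }
  p <- unlist(as.list(counts)) / nw
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

# naive chromatic RQA: materialize the full T x T matrix and scan it with
# explicit loops
brute_rqa <- function(states, target = c("oral_tactile",
                                         "object_distraction",
                                         "social_interactive",
                                         "motor_stimulatory", "distancing"),
                      v_min = 3, loi_excluded = TRUE) {
  T <- length(states)
  R <- matrix(FALSE, T, T)
  for (i in seq_len(T)) {
    for (j in seq_len(T)) {
      if (i == j && loi_excluded) next
      if (states[i] %in% target && states[i] == states[j]) R[i, j] <- TRUE
    }
  }
  total <- sum(R)
  denom <- if (loi_excluded) T^2 - T else T^2
  rr <- 100 * total / denom
  lens <- integer(0)
  for (j in seq_len(T)) {
    run <- 0
    for (i in seq_len(T)) {
      if (R[i, j]) {
        run <- run + 1
      } else {
        if (run > 0) lens <- c(lens, run)
        run <- 0
      }
    }
    if (run > 0) lens <- c(lens, run)
  }
  lam <- if (total == 0) 0 else 100 * sum(lens[lens >= v_min]) / total
  q <- lens[lens >= v_min]
  tt <- if (length(q) == 0) NA_real_ else sum(q) / length(q)
  # bouts by manual scan; block sizes over ordered same-state bout pairs
  bout_state <- character(0); bout_len <- integer(0)
  cur <- states[1]; run <- 1
  for (i in seq_len(T)[-1]) {
    if (states[i] == cur) {
      run <- run + 1
    } else {
      bout_state <- c(bout_state, cur); bout_len <- c(bout_len, run)
      cur <- states[i]; run <- 1
    }
  }
  bout_state <- c(bout_state, cur); bout_len <- c(bout_len, run)
  keep <- bout_state %in% target
  bout_state <- bout_state[keep]; bout_len <- bout_len[keep]
  if (length(bout_len) == 0) {
    entb <- NA_real_
  } else {
    sizes <- integer(0)
    for (i in seq_along(bout_len)) {
      for (j in seq_along(bout_len)) {
        if (bout_state[i] == bout_state[j]) {
          sizes <- c(sizes, bout_len[i] * bout_len[j])
        }
      }
    }
    tab <- table(sizes)
    p <- as.numeric(tab) / sum(tab)
    entb <- -sum(p * log2(p))
  }
  list(rr = rr, lam = lam, tt = tt, entb = entb, lines = sort(lens),
       total = total)
}

# amplitude of a (near-)sinusoidal series, steady-state section
sine_amplitude <- function(y, trim = 0.2) {
  n <- length(y)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  sqrt(2 * mean(y[i]^2))
}

rand_states <- function(T, alphabet, p = NULL) {
  sample(alphabet, T, replace = TRUE, prob = p)
}

expect_same_rqa <- function(states, v_min = 3, loi_excluded = TRUE) {
  got <- rqa_measures(states, v_min = v_min, loi_excluded = loi_excluded)
  want <- brute_rqa(states, v_min = v_min, loi_excluded = loi_excluded)
  expect_equal(got$rr, want$rr, tolerance = 1e-12)
  expect_equal(got$lam, want$lam, tolerance = 1e-12)
  expect_equal(got$tt, want$tt, tolerance = 1e-12)
  expect_equal(got$entb, want$entb, tolerance = 1e-12)
}
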