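# Chromatic auto-recurrence quantification of categorical behaviour
# sequences. A point (i, j) recurs iff the state at i equals the state at
# j AND that state belongs to the target (emotional self-regulation) set;
# "none" never recurs. Embedding is dimension 1, delay 1, radius 0 (exact
# state identity), the standard convention for categorical RQA.

ER_STATES <- c("oral_tactile", "object_distraction", "social_interactive",
               "motor_stimulatory", "distancing")
BEHAVIOUR_ALPHABET <- c(ER_STATES, "none")

#' Construct a 1 Hz categorical behaviour sequence
#'
#' A second-by-second coding of infant emotional self-regulation behaviour
#' over a still-face phase: five ER states (oral-tactile self-comforting,
#' attentional distraction via object manipulation, social interactive,
#' motor stimulatory, distancing) plus "none". Complete 2-min phases have
#' 120 samples.
#'
#' @param states character vector over the fixed alphabet.
#' @param phase phase label (normally SF1 or SF2).
#' @param participant,group optional metadata.
#' @return object of class `behaviour_sequence`.
#' @export
behaviour_sequence <- function(states, phase = "SF1",
                               participant = NA_character_,
                               group = NA_character_) {
  states <- as.character(states)
  bad <- setdiff(unique(states), BEHAVIOUR_ALPHABET)
  if (length(bad) > 0) stop("unknown state label(s): ",
                            paste(bad, collapse = ", "))
  if (length(states) < 1) stop("empty sequence")
  structure(list(states = states, phase = phase, participant = participant,
                 group = group),
            class = "behaviour_sequence")
}

#' Build a chromatic auto-recurrence plot
#'
#' @param seq a `behaviour_sequence` or bare character vector of states.
#' @param target_states states allowed to generate recurrences (default:
#'   the five ER states; "none" is always excluded by default).
#' @param loi_excluded drop the line of identity (main diagonal), the
#'   auto-RQA standard (default TRUE).
#' @return object of class `recurrence_plot`: logical T x T matrix `R`,
#'   the state labels, and the configuration.
#' @export
build_recurrence_plot <- function(seq, target_states = ER_STATES,
                                  loi_excluded = TRUE) {
  states <- if (inherits(seq, "behaviour_sequence")) seq$states
            else as.character(seq)
  if (length(states) < 1) stop("empty sequence")
  bad <- setdiff(unique(states), BEHAVIOUR_ALPHABET)
  if (length(bad) > 0) stop("unknown state label(s): ",
                            paste(bad, collapse = ", "))
  in_target <- states %in% target_states
  R <- outer(states, states, "==") & outer(in_target, in_target, "&")
  if (loi_excluded) diag(R) <- FALSE
  structure(list(R = R, states = states, target_states = target_states,
                 loi_excluded = loi_excluded),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> T = %d, %d recurrent points (LOI %s)\n",
              length(x$states), sum(x$R),
              if (x$loi_excluded) "excluded" else "included"))
  invisible(x)
}

#' Recurrence rate
#'
#' Percentage of possible plot points that are recurrent — the extent the
#' infant repeats an ER behaviour. The denominator is `T^2 - T` with the
#' line of identity excluded, `T^2` otherwise.
#'
#' @param rp a `recurrence_plot`.
#' @return percentage in `[0, 100]`.
#' @export
recurrence_rate <- function(rp) {
  T <- length(rp$states)
  if (rp$loi_excluded && T < 2) stop("need T >= 2 with LOI excluded")
  denom <- if (rp$loi_excluded) T^2 - T else T^2
  100 * sum(rp$R) / denom
}

#' Vertical line lengths of a recurrence plot
#'
#' Maximal runs of consecutive recurrent points down each column, in
#' samples (seconds at 1 Hz). The gap left by an excluded line of identity
#' breaks runs. Lines truncated by the plot border count at their observed
#' length.
#'
#' @param rp a `recurrence_plot`.
#' @return integer vector (multiset) of line lengths, all >= 1.
#' @export
vertical_lines <- function(rp) {
  lens <- integer(0)
  for (j in seq_len(ncol(rp$R))) {
    r <- rle(rp$R[, j])
    lens <- c(lens, r$lengths[r$values])
  }
  lens
}

#' Laminarity
#'
#' Percentage of recurrent points lying on vertical lines of at least
#' `v_min` samples — whether ER behaviours, when they occur, persist for a
#' substantial time (3 s or longer by default) rather than appearing as
#' isolated recurrences. Defined as 0 when the plot has no recurrent
#' points.
#'
#' @param lines vertical line lengths from [vertical_lines()].
#' @param total_recurrent total number of recurrent points in the plot.
#' @param v_min minimum laminar length in samples (default 3).
#' @return percentage in `[0, 100]`.
#' @export
laminarity <- function(lines, total_recurrent, v_min = 3) {
  if (total_recurrent == 0) return(0)
  100 * sum(lines[lines >= v_min]) / total_recurrent
}

#' Trapping time
#'
#' Mean length of vertical lines of at least `v_min` samples: the average
#' time spent in a stable behavioural state, in seconds at 1 Hz. Reported
#' as missing (`NA`), not zero, when no line qualifies, so downstream
#' averaging is not biased.
#'
#' @inheritParams laminarity
#' @return mean qualifying line length in seconds, or `NA_real_`.
#' @export
trapping_time <- function(lines, v_min = 3) {
  q <- lines[lines >= v_min]
  if (length(q) == 0) return(NA_real_)
  mean(q)
}

# maximal same-state bout lengths for states in the target set, with the
# bout runs in sequence order
target_bouts <- function(states, target_states) {
  r <- rle(states)
  keep <- r$values %in% target_states
  list(state = r$values[keep], len = r$lengths[keep])
}

#' Block entropy (ENTb)
#'
#' The recurrence plot of a categorical sequence is a union of rectangular
#' blocks: every ordered pair of same-state ER bouts of lengths `a` and
#' `b` contributes an `a x b` block (a bout paired with itself gives the
#' `a x a` block on the diagonal). ENTb is the Shannon entropy, in bits,
#' of the distribution of block sizes (points per block, integer bins)
#' over all ordered bout pairs. It indexes the flexibility of bout
#' patterning: all bouts of one length give a single block size and
#' ENTb = 0; a mix of bout lengths spreads the size distribution.
#'
#' Block sizes are classified with the line of identity included
#' (`a x a`, not `a^2 - a`), so the sum of block sizes equals the number
#' of recurrent points of the LOI-included plot; excluding the LOI from
#' measure counts does not change which block a point belongs to.
#'
#' @param rp a `recurrence_plot`.
#' @return entropy in bits per bin, or `NA_real_` when the sequence
#'   contains no target-state bout.
#' @export
block_entropy <- function(rp) {
  b <- target_bouts(rp$states, rp$target_states)
  if (length(b$len) == 0) return(NA_real_)
  sizes <- integer(0)
  for (st in unique(b$state)) {
    lens <- b$len[b$state == st]
    sizes <- c(sizes, as.vector(outer(lens, lens)))
  }
  p <- table(sizes) / length(sizes)
  -sum(p * log2(p))
}

#' All chromatic RQA measures for one behaviour sequence
#'
#' Bundles recurrence rate, laminarity, trapping time and block entropy
#' with the parameters used to produce them.
#'
#' @param seq a `behaviour_sequence` or character vector.
#' @param target_states see [build_recurrence_plot()].
#' @param v_min minimum laminar length in samples (default 3).
#' @param loi_excluded exclude the line of identity (default TRUE).
#' @return list of class `rqa_measures`: `rr`, `lam`, `tt`, `entb`,
#'   `v_min`, `loi_excluded`, `n_recurrent`, `T`.
#' @export
rqa_measures <- function(seq, target_states = ER_STATES, v_min = 3,
                         loi_excluded = TRUE) {
  rp <- build_recurrence_plot(seq, target_states, loi_excluded)
  lines <- vertical_lines(rp)
  total <- sum(rp$R)
  structure(
    list(rr = recurrence_rate(rp),
         lam = laminarity(lines, total, v_min),
         tt = trapping_time(lines, v_min),
         entb = block_entropy(rp),
         v_min = v_min, loi_excluded = loi_excluded,
         n_recurrent = total, T = length(rp$states)),
    class = "rqa_measures"
  )
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf(
    "<rqa_measures> RR %.2f%%  LAM %.2f%%  TT %s s  ENTb %s bits/bin\n",
    x$rr, x$lam,
    if (is.na(x$tt)) "NA" else sprintf("%.2f", x$tt),
    if (is.na(x$entb)) "NA" else sprintf("%.3f", x$entb)))
  invisible(x)
}
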