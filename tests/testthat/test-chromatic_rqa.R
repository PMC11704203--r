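ER <- c("oral_tactile", "object_distraction", "social_interactive",
        "motor_stimulatory", "distancing")

test_that("recurrence plots obey the chromatic restriction", {
  expect_equal(sum(build_recurrence_plot(rep("none", 10))$R), 0)
  expect_error(build_recurrence_plot(c("oral_tactile", "chewing")),
               "unknown state")

  # T = 4, (A, A, none, A): recurrent pairs {(1,2),(1,4),(2,4)} + symmetric
  rp <- build_recurrence_plot(c("distancing", "distancing", "none",
                                "distancing"))
  expect_equal(sum(rp$R), 6)
  expect_true(rp$R[1, 2] && rp$R[1, 4] && rp$R[2, 4])
  expect_false(any(diag(rp$R)))
  expect_identical(rp$R, t(rp$R))
  expect_equal(recurrence_rate(rp), 50)

  # single ER state, T = 120: all off-diagonal points recurrent
  rp2 <- build_recurrence_plot(rep("motor_stimulatory", 120))
  expect_equal(sum(rp2$R), 120^2 - 120)
  expect_equal(recurrence_rate(rp2), 100)

  # LOI included on request
  rp3 <- build_recurrence_plot(rep("motor_stimulatory", 10),
                               loi_excluded = FALSE)
  expect_equal(recurrence_rate(rp3), 100)
  expect_error(recurrence_rate(build_recurrence_plot("none")), "T >= 2")
})

test_that("vertical lines are maximal column runs broken by the LOI gap", {
  # single-state T = 5: each column has runs (k-1, 5-k) around the diagonal
  rp <- build_recurrence_plot(rep("distancing", 5))
  expect_equal(sort(vertical_lines(rp)),
               sort(brute_rqa(rep("distancing", 5))$lines))

  # alternating with none: no laminarity
  alt <- rep(c("distancing", "none"), 10)
  expect_true(all(vertical_lines(build_recurrence_plot(alt)) == 1))

  # one 3-bout: off-diagonal columns see runs of length 3
  s <- c(rep("oral_tactile", 3), rep("none", 7))
  lines <- vertical_lines(build_recurrence_plot(s))
  expect_equal(sort(lines), sort(brute_rqa(s)$lines))
  # sum of all line lengths equals total recurrent points
  expect_equal(sum(lines), sum(build_recurrence_plot(s)$R))
})

test_that("laminarity and trapping time follow their definitions", {
  expect_equal(laminarity(rep(1, 7), 7), 0)
  expect_equal(laminarity(c(4, 5), 9), 100)
  expect_equal(laminarity(c(3, 1, 1), 5), 60)
  expect_equal(laminarity(integer(0), 0), 0)
  expect_equal(trapping_time(c(3, 5)), 4)
  expect_true(is.na(trapping_time(c(2, 2))))
})

test_that("block entropy reflects bout-length diversity", {
  # all ER bouts identical length: one block size, zero entropy
  s <- rep(c(rep("oral_tactile", 4), rep("none", 4)), 10)
  expect_equal(block_entropy(build_recurrence_plot(s)), 0)

  # two blocks of different sizes, equally frequent: exactly 1 bit
  s2 <- c("oral_tactile", "none", rep("distancing", 2))
  expect_equal(block_entropy(build_recurrence_plot(s2)), 1)

  expect_true(is.na(block_entropy(build_recurrence_plot(rep("none", 5)))))

  # sum of block sizes equals recurrent points of the LOI-included plot
  set.seed(21)
  for (i in 1:5) {
    s <- rand_states(60, c(ER[1:3], "none"))
    rp <- build_recurrence_plot(s)
    b <- rle(s)
    sizes <- unlist(lapply(unique(b$values[b$values %in% ER]), function(st) {
      lens <- b$lengths[b$values == st]
      as.vector(outer(lens, lens))
    }))
    rp_loi <- build_recurrence_plot(s, loi_excluded = FALSE)
    expect_equal(sum(sizes), sum(rp_loi$R))
  }

  # geometric bout lengths beat fixed bout lengths, every seed
  for (seed in 1:20) {
    fix <- gen_behaviour_sequence(behaviour_scenario(bout_dist = "fixed",
                                                     seed = seed))
    geo <- gen_behaviour_sequence(behaviour_scenario(bout_dist = "geometric",
                                                     seed = seed))
    e_fix <- rqa_measures(fix)$entb
    e_geo <- rqa_measures(geo)$entb
    expect_gt(e_geo, e_fix)
  }
})

test_that("rqa_measures equals the naive full-matrix oracle", {
  expect_same_rqa(rep("none", 12))
  expect_same_rqa(rep("social_interactive", 120))
  set.seed(22)
  for (i in 1:25) {
    T <- sample(5:50, 1)
    s <- rand_states(T, c(ER[1:2], "none"), p = c(0.4, 0.3, 0.3))
    expect_same_rqa(s)
    expect_same_rqa(s, v_min = 2)
    expect_same_rqa(s, loi_excluded = FALSE)
  }
  # all-"none": RR 0, LAM 0, TT and ENTb missing (not zero)
  m <- rqa_measures(rep("none", 120))
  expect_equal(m$rr, 0)
  expect_equal(m$lam, 0)
  expect_true(is.na(m$tt) && is.na(m$entb))
})

test_that("RR and LAM are invariant under relabeling the ER alphabet", {
  set.seed(23)
  s <- rand_states(80, c(ER, "none"))
  relab <- setNames(c(ER[c(3, 1, 5, 2, 4)], "none"), c(ER, "none"))
  m1 <- rqa_measures(s)
  m2 <- rqa_measures(unname(relab[s]))
  expect_equal(m1$rr, m2$rr)
  expect_equal(m1$lam, m2$lam)
})

test_that("RR grows as none-samples convert to the modal ER state", {
  set.seed(24)
  s <- rand_states(100, c(ER[1:2], "none"), p = c(0.3, 0.2, 0.5))
  modal <- names(which.max(table(s[s %in% ER])))
  rrs <- numeric(0)
  repeat {
    rrs <- c(rrs, rqa_measures(s)$rr)
    none_at <- which(s == "none")
    if (length(none_at) == 0) break
    s[none_at[1]] <- modal
  }
  expect_true(all(diff(rrs) >= 0))
})
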