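test_that("stage amounts use non-artifact denominators and merge A2/3", {
  # hand arithmetic: 40 A1 + 20 B2/3 in one minute
  s <- stage_sequence(c(rep("A1", 40), rep("B2/3", 20)))
  a <- stage_amounts(s)
  expect_equal(a["1", "A1"], 40 * 100 / 60, tolerance = 1e-12)
  expect_equal(a["1", "B2/3"], 20 * 100 / 60, tolerance = 1e-12)
  expect_equal(a["total", "A1"] + a["total", "B2/3"], 100)

  # denominator is the non-artifact count: 30 artifact, 15 of remaining C
  st <- c(rep("C", 15), rep("A1", 15), rep("0", 30))
  art <- c(rep(FALSE, 30), rep(TRUE, 30))
  a2 <- stage_amounts(stage_sequence(st, artifact = art))
  expect_equal(a2["1", "n_nonartifact"], 30)
  expect_equal(a2["1", "C"], 50)

  # A2 + A3 report as one group
  a3 <- stage_amounts(stage_sequence(rep(c("A2", "A3"), 30)))
  expect_equal(a3["total", "A2/3"], 100)

  expect_error(stage_amounts(stage_sequence(rep("A1", 60),
                                            artifact = rep(TRUE, 60))),
               "artifact")
})

test_that("amount rows sum to 100 for random sequences with artifacts", {
  set.seed(401)
  for (i in 1:50) {
    s <- random_sequence(300, p_artifact = runif(1, 0, 0.3))
    if (all(s$artifact)) next
    a <- stage_amounts(s)
    sums <- rowSums(a[, c("0", "A1", "A2/3", "B1", "B2/3", "C")])
    ok <- a$n_nonartifact > 0
    expect_equal(sums[ok], rep(100, sum(ok)), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_true(all(is.na(sums[!ok])))
  }
})

test_that("MVV averages the fixed scores over non-artifact seconds", {
  expect_equal(mean_vigilance_value(stage_sequence(rep("0", 120)))$total, 7)
  expect_equal(mean_vigilance_value(stage_sequence(rep("C", 120)))$total, 1)
  s <- stage_sequence(rep(c("A1", "B1"), 60)) # scores 6 and 3
  m <- mean_vigilance_value(s)
  expect_equal(m$total, 4.5)
  expect_equal(m$per_minute, rep(4.5, 2))
  # artifact seconds are excluded from the mean
  s2 <- stage_sequence(c(rep("A1", 30), rep("C", 30)),
                       artifact = c(rep(FALSE, 30), rep(TRUE, 30)))
  expect_equal(mean_vigilance_value(s2)$total, 6)
})

test_that("minute criteria use inclusive boundaries and imply correctly", {
  # a full minute of B2/3 fulfils II and III but not I or IV
  mc <- minute_criteria(stage_sequence(rep("B2/3", 60)))
  expect_true(mc$crit_II[1] && mc$crit_III[1])
  expect_false(mc$crit_I_0A[1] || mc$crit_IV[1])

  # boundary: exactly 20/60 B seconds fulfils criterion II (1/3 inclusive)
  mc2 <- minute_criteria(stage_sequence(c(rep("B1", 20), rep("A1", 40))))
  expect_true(mc2$crit_II[1])
  expect_false(mc2$crit_III[1])
  mc2b <- minute_criteria(stage_sequence(c(rep("B1", 19), rep("A1", 41))))
  expect_false(mc2b$crit_II[1])

  # one C second: criterion IV; 59/60 A1 still fulfils I (2/3 inclusive)
  mc3 <- minute_criteria(stage_sequence(c("C", rep("A1", 59))))
  expect_true(mc3$crit_IV[1])
  expect_true(mc3$crit_I_0A1[1])

  # implication invariants on random minutes
  set.seed(402)
  for (i in 1:40) {
    mc <- minute_criteria(random_sequence(60))
    if (!mc$evaluable[1]) next
    expect_true(!mc$crit_III[1] || mc$crit_II[1])
    expect_true(!mc$crit_I_0A1[1] || mc$crit_I_0A[1])
  }

  # blocks with too few non-artifact seconds are unevaluable
  art <- c(rep(TRUE, 45), rep(FALSE, 15))
  mc4 <- minute_criteria(stage_sequence(rep("A1", 60), artifact = art))
  expect_false(mc4$evaluable[1])
  expect_true(is.na(mc4$crit_II[1]))
})

test_that("ASS reproduces the printed anchor scores", {
  expect_equal(arousal_stability_score(course_with())$score, 14)
  only_0a <- stage_sequence(rep(c(rep("A1", 30), rep("A2", 30)), 20))
  expect_equal(arousal_stability_score(only_0a)$score, 13)
  first_c_q4 <- course_with(list(list(at = 17 * 60 + 30, stage = "C")))
  expect_equal(arousal_stability_score(first_c_q4)$score, 4)
  first_c_q1 <- course_with(list(list(at = 90, stage = "C")))
  expect_equal(arousal_stability_score(first_c_q1)$score, 1)
})

test_that("every ASS score in 1..14 is reachable by construction", {
  seqs <- list()
  for (q in 1:4) {
    # criterion IV in quartile q -> scores 1..4
    seqs[[q]] <- course_with(list(list(at = (q - 1) * 300 + 30, stage = "C")))
    # criterion III in quartile q -> scores 5..8
    at <- (q - 1) * 300 + 1:20
    seqs[[4 + q]] <- course_with(list(list(at = at, stage = "B2/3")))
    # criterion II (B1 only) in quartile q -> scores 9..12
    seqs[[8 + q]] <- course_with(list(list(at = at, stage = "B1")))
  }
  seqs[[13]] <- stage_sequence(rep(c("A1", "A2"), 600))
  seqs[[14]] <- course_with()
  scores <- vapply(seqs, function(s) arousal_stability_score(s)$score,
                   integer(1))
  expect_equal(scores, 1:14)
  # decisive criterion bands match the score bands
  dec <- vapply(seqs, function(s) {
    arousal_stability_score(s)$decisive_criterion
  }, character(1))
  expect_equal(dec, c(rep("IV", 4), rep("III", 4), rep("II", 4),
                      "none", "none"))
})

test_that("ASS refuses undefined inputs", {
  expect_error(arousal_stability_score(stage_sequence(rep("A1", 900))),
               "divisible")
  all_art <- stage_sequence(rep("A1", 1200), artifact = rep(TRUE, 1200))
  expect_error(arousal_stability_score(all_art), "no evaluable")
  # one quartile entirely unevaluable
  art <- rep(FALSE, 1200); art[301:600] <- TRUE
  expect_error(arousal_stability_score(stage_sequence(rep("A1", 1200),
                                                      artifact = art)),
               "quartile 2")
})

test_that("total amounts and MVV are invariant to artifact insertion", {
  set.seed(403)
  base <- random_sequence(600)
  a0 <- stage_amounts(base)["total", ]
  m0 <- mean_vigilance_value(base)$total
  # insert 120 artifact seconds at random positions
  pos <- sort(sample(720, 120))
  st <- rep(NA_character_, 720); art <- rep(FALSE, 720)
  art[pos] <- TRUE
  st[!art] <- base$stages
  ins <- stage_sequence(ifelse(is.na(st), "A1", st), artifact = art)
  a1 <- stage_amounts(ins)["total", ]
  expect_equal(unlist(a1[c("0", "A1", "A2/3", "B1", "B2/3", "C")]),
               unlist(a0[c("0", "A1", "A2/3", "B1", "B2/3", "C")]),
               tolerance = 1e-12)
  expect_equal(mean_vigilance_value(ins)$total, m0, tolerance = 1e-12)
})
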