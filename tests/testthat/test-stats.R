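test_that("Mann-Whitney U reproduces enumerable examples", {
  # complete separation: U = 0, one-tailed p = 1/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), tail = "less")
  expect_equal(r$statistic[["U"]], 0)
  expect_equal(r$p_value, 1 / 20)
  expect_true(r$exact)
  # identical multisets: two-tailed p = 1
  r2 <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5), tail = "two")
  expect_equal(r2$p_value, 1)
  expect_equal(r2$statistic[["U"]], 8) # n_a n_b / 2
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact U p-values match full enumeration, with and without ties", {
  set.seed(601)
  for (i in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    vals <- if (i %% 2 == 0) sample(1:5, na + nb, replace = TRUE)
            else rnorm(na + nb)
    a <- vals[1:na]; b <- vals[-(1:na)]
    for (tail in c("two", "greater", "less")) {
      expect_equal(mann_whitney_u(a, b, tail = tail)$p_value,
                   oracle_mw_p(a, b, tail), tolerance = 1e-12)
    }
  }
})

test_that("exact U matches wilcox.test in tie-free cases", {
  set.seed(602)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(7)
    got <- mann_whitney_u(a, b, tail = "greater")
    ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(got$statistic[["U"]], unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample U uses a tie-corrected normal approximation", {
  set.seed(603)
  a <- rnorm(30); b <- rnorm(25) + 0.8
  got <- mann_whitney_u(a, b, tail = "less")
  ref <- stats::wilcox.test(a, b, alternative = "less", correct = TRUE,
                            exact = FALSE)
  expect_false(got$exact)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_lt(got$z, 0) # a shifted left => negative standardised effect
})

test_that("chi-square matches hand computation and halves one-tailed p", {
  expect_equal(chi_square_independence(rbind(c(10, 0),
                                             c(0, 10)))$statistic[["X2"]],
               20)
  tab <- rbind(c(12, 8, 5), c(6, 9, 10))
  r2 <- chi_square_independence(tab, tail = "two")
  r1 <- chi_square_independence(tab, tail = "one")
  expect_equal(r1$p_value, r2$p_value / 2)
  expect_equal(r2$df, 2)
  # invariance to row swap; proportional table gives 0
  expect_equal(chi_square_independence(tab[2:1, ])$statistic[["X2"]],
               r2$statistic[["X2"]])
  expect_equal(chi_square_independence(rbind(c(10, 20),
                                             c(5, 10)))$statistic[["X2"]],
               0, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "zero margin")
})

test_that("Spearman reproduces monotone anchors and the exact null", {
  expect_equal(spearman_test(1:6, 2 * (1:6) + 3)$statistic[["rho"]], 1)
  expect_equal(spearman_test(1:6, rev(1:6))$statistic[["rho"]], -1)
  expect_error(spearman_test(1:6, rep(2, 6)), "constant")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
  set.seed(604)
  for (i in 1:12) {
    n <- sample(5:7, 1)
    x <- rnorm(n)
    y <- if (i %% 2 == 0) sample(1:3, n, replace = TRUE) else rnorm(n)
    for (tail in c("two", "greater", "less")) {
      expect_equal(spearman_test(x, y, tail = tail)$p_value,
                   oracle_spearman_p(x, y, tail), tolerance = 1e-12)
    }
  }
})

test_that("exact Spearman matches cor.test in tie-free cases at n = 8, 9", {
  set.seed(605)
  for (n in c(8, 9)) {
    for (i in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      got <- spearman_test(x, y, tail = "greater")
      ref <- stats::cor.test(x, y, method = "spearman",
                             alternative = "greater", exact = TRUE)
      expect_equal(got$statistic[["rho"]], unname(ref$estimate))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("median split balances, thresholds and warns as documented", {
  ms <- median_split(c(60, 70, 80, 90))
  expect_equal(ms$threshold, 75)
  expect_equal(ms$low, 1:2)
  expect_equal(ms$high, 3:4)
  # values equal to the median are alternated into balanced halves
  ms2 <- median_split(c(1, 2, 2, 3))
  expect_equal(lengths(ms2[c("low", "high")]), c(low = 2L, high = 2L))
  expect_warning(median_split(rep(5, 6)), "median")
  # 34 distinct simulated sleep-efficiency values split 17/17
  set.seed(606)
  se <- round(runif(34, 40, 95), 1)
  while (anyDuplicated(se)) se <- round(runif(34, 40, 95), 1)
  ms3 <- median_split(se)
  expect_equal(lengths(ms3[c("low", "high")]), c(low = 17L, high = 17L))
  expect_true(all(se[ms3$high] > ms3$threshold))
  expect_true(all(se[ms3$low] < ms3$threshold))
})
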