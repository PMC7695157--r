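# Cohort-level test machinery: one-tailed Mann-Whitney U with exact
# small-sample p-values, chi-square on contingency tables, Spearman
# correlation with exact permutation p at small n, and the median split.

vig_test <- function(method, statistic, p_value, tail, n, z = NA_real_,
                     df = NA_real_, exact = NA, estimate = NULL, note = NULL) {
  structure(list(method = method, statistic = statistic, z = z, df = df,
                 p_value = p_value, tail = tail, n = n, exact = exact,
                 estimate = estimate, note = note),
            class = "vig_test")
}

#' @export
print.vig_test <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
              collapse = ", ")
  cat(sprintf("<vig_test> %s: %s, p = %.4g (%s-tailed%s), n = %s\n",
              x$method, st, x$p_value, x$tail,
              if (isTRUE(x$exact)) ", exact" else "",
              paste(x$n, collapse = "/")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# flatten a vig_test for JSON reports
as_list_vig_test <- function(x) {
  out <- list(method = x$method, p_value = x$p_value, tail = x$tail,
              n = as.list(x$n), exact = x$exact)
  out[names(x$statistic)] <- as.numeric(x$statistic)
  if (!is.na(x$z)) out$z <- x$z
  if (!is.na(x$df)) out$df <- x$df
  if (!is.null(x$estimate)) out[names(x$estimate)] <- as.numeric(x$estimate)
  if (!is.null(x$note)) out$note <- x$note
  out
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Computes the U statistic for the first sample with midrank tie handling.
#' For `length(a) + length(b) <= exact_limit` (default 16) the p-value is
#' exact, obtained by enumerating all group assignments (this handles tied
#' data correctly); otherwise a normal approximation with tie correction and
#' continuity correction is used. A standardised `z` is always reported.
#'
#' @param a,b numeric samples.
#' @param tail `"two"`, or one-sided `"greater"` / `"less"` (is `a` shifted
#'   right / left of `b`); one-sided tests are meant for directed
#'   hypotheses.
#' @param exact_limit maximal total n for exact enumeration.
#' @return A `vig_test` with statistic `U` (and `U_other = n_a n_b - U`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), tail = "less")$p_value # 1/20
mann_whitney_u <- function(a, b, tail = c("two", "greater", "less"),
                           exact_limit = 16) {
  tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) fail("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) fail("samples must not contain NA")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # midranks
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  # normal approximation with tie and continuity correction (z is always
  # reported; it is the effect measure printed alongside U in field reports)
  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- 0.5
  z <- if (sig2 > 0) {
    num <- u_obs - mu
    (num - sign(num) * min(cc, abs(num))) / sqrt(sig2)
  } else 0
  exact <- n <= exact_limit
  if (exact) {
    combos <- combn(n, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_greater <- mean(u_all >= u_obs - eps)
    p_less <- mean(u_all <= u_obs + eps)
  } else {
    if (sig2 <= 0) fail("all observations tied; U test degenerate")
    p_greater <- pnorm((u_obs - mu - cc) / sqrt(sig2), lower.tail = FALSE)
    p_less <- pnorm((u_obs - mu + cc) / sqrt(sig2))
  }
  p <- switch(tail,
              two = min(1, 2 * min(p_greater, p_less)),
              greater = p_greater,
              less = p_less)
  vig_test("Mann-Whitney U",
           statistic = c(U = u_obs, U_other = na * nb - u_obs),
           p_value = p, tail = tail, n = c(n_a = na, n_b = nb),
           z = z, exact = exact)
}

#' Pearson chi-square test of independence
#'
#' Thin wrapper around [stats::chisq.test()] without continuity correction.
#' For directed hypotheses on a contingency table the reported one-tailed
#' p-value is half the upper-tail chi-square probability.
#'
#' @param table matrix of counts (groups x categories).
#' @param tail `"two"` (the usual upper-tail chi-square p) or `"one"`.
#' @return A `vig_test` with statistic `X2` and degrees of freedom; a note
#'   flags expected counts below 5.
#' @export
#' @examples
#' chi_square_independence(rbind(c(10, 0), c(0, 10)))$statistic[["X2"]] # 20
chi_square_independence <- function(table, tail = c("two", "one")) {
  tail <- match.arg(tail)
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    fail("contingency table has a zero margin; chi-square is undefined")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  note <- if (any(res$expected < 5)) {
    sprintf("%d expected count(s) below 5; chi-square approximation is weak",
            sum(res$expected < 5))
  }
  p2 <- unname(res$p.value)
  vig_test("Pearson chi-square",
           statistic = c(X2 = unname(res$statistic)),
           p_value = if (tail == "one") p2 / 2 else p2,
           tail = tail, n = sum(table), df = unname(res$parameter),
           exact = FALSE, note = note)
}

# cache of permutation matrices for exact Spearman p-values
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  pm <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    }))
  }
  .perm_cache[[key]] <- pm
  pm
}

#' Spearman rank correlation with exact permutation p at small n
#'
#' Rank correlation on midranks. For `n <= exact_limit` (default 9) the
#' p-value is exact, from the full permutation distribution of the rank
#' inner product (valid with ties); otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 4` after removing incomplete
#'   pairs.
#' @param tail `"two"`, `"greater"` (rho > 0) or `"less"` (rho < 0).
#' @param exact_limit maximal n for exact enumeration.
#' @return A `vig_test` with statistic `rho`.
#' @export
#' @examples
#' spearman_test(1:6, c(2, 3, 4, 7, 8, 9), tail = "greater")$statistic
spearman_test <- function(x, y, tail = c("two", "greater", "less"),
                          exact_limit = 9) {
  tail <- match.arg(tail)
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  n <- length(x)
  if (n < 4L) fail("Spearman correlation needs at least 4 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    fail("Spearman correlation is undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  exact <- n <= exact_limit
  if (exact) {
    pm <- perm_matrix(n)
    # the rank inner product is monotone in rho for fixed marginal ranks
    t_all <- as.vector(matrix(ry[pm], nrow = nrow(pm)) %*% rx)
    t_obs <- sum(rx * ry)
    eps <- 1e-9
    p_greater <- mean(t_all >= t_obs - eps)
    p_less <- mean(t_all <= t_obs + eps)
  } else {
    if (abs(rho) >= 1) {
      p_greater <- if (rho > 0) 0 else 1
      p_less <- if (rho > 0) 1 else 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p_greater <- pt(tt, df = n - 2, lower.tail = FALSE)
      p_less <- pt(tt, df = n - 2)
    }
  }
  p <- switch(tail,
              two = min(1, 2 * min(p_greater, p_less)),
              greater = p_greater,
              less = p_less)
  vig_test("Spearman rank correlation", statistic = c(rho = rho),
           p_value = p, tail = tail, n = n, exact = exact)
}

#' Median split of a covariate into low and high subgroups
#'
#' The threshold is the sample median; values above it go to the `high`
#' group, values below to `low`. Values equal to the median are assigned
#' alternately to whichever group is currently smaller (low first on a
#' balanced tie), which yields equal halves for even n — also when the
#' median value itself occurs in the data.
#'
#' @param values numeric vector, `n >= 2`.
#' @return A list: `threshold`, `group` (factor `"low"`/`"high"` per input
#'   value) and the index vectors `low` and `high`.
#' @export
#' @examples
#' median_split(c(60, 70, 80, 90))
median_split <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) fail("median split needs at least 2 values")
  if (anyNA(values)) fail("values must not contain NA")
  thr <- median(values)
  grp <- rep(NA_character_, length(values))
  grp[values > thr] <- "high"
  grp[values < thr] <- "low"
  eq <- which(values == thr)
  if (length(eq) == length(values)) {
    warning("all values equal the median; applying an arbitrary balanced split")
  }
  for (i in eq) {
    n_low <- sum(grp == "low", na.rm = TRUE)
    n_high <- sum(grp == "high", na.rm = TRUE)
    grp[i] <- if (n_low <= n_high) "low" else "high"
  }
  grp <- factor(grp, levels = c("low", "high"))
  list(threshold = thr, group = grp,
       low = which(grp == "low"), high = which(grp == "high"))
}
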