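# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

# --- Mann-Whitney oracle: full enumeration of group assignments, U counted
#     directly as the number of (a_i > b_j) pairs (+ 1/2 per tie).
oracle_mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_mw_p <- function(a, b, tail) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_obs <- oracle_mw_u(a, b)
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) {
    oracle_mw_u(pool[idx], pool[-idx])
  })
  eps <- 1e-9
  pg <- mean(u_all >= u_obs - eps)
  pl <- mean(u_all <= u_obs + eps)
  switch(tail,
         two = min(1, 2 * min(pg, pl)),
         greater = pg,
         less = pl)
}

# --- Spearman oracle: loop over all permutations of y (generated by an
#     iterative next-permutation scheme), rho via stats::cor on ranks.
oracle_all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  prev <- oracle_all_perms(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[prev], nrow = nrow(prev)))
  })
  do.call(rbind, blocks)
}

oracle_spearman_p <- function(x, y, tail) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  pm <- oracle_all_perms(n)
  rho_all <- vapply(seq_len(nrow(pm)), function(i) {
    stats::cor(rx, ry[pm[i, ]])
  }, numeric(1))
  eps <- 1e-9
  pg <- mean(rho_all >= rho_obs - eps)
  pl <- mean(rho_all <= rho_obs + eps)
  switch(tail,
         two = min(1, 2 * min(pg, pl)),
         greater = pg,
         less = pl)
}

# --- Markov first-passage oracle: probability that the minute chain first
#     reaches state C within minutes 2..m_max, by forward enumeration.
oracle_first_c_prob <- function(params, m_max) {
  P <- build_stage_chain(params)
  pv <- rep(0, 7)
  pv[params$start_score] <- 1
  hit <- 0
  for (m in seq.int(2, m_max)) {
    hit <- hit + sum(pv * P[, 1])
    pv <- as.vector(pv %*% P)
    pv[1] <- 0
  }
  hit
}

# --- course builders -------------------------------------------------------

# a 20-min all-A1 sequence with selected seconds overridden
course_with <- function(overrides = list(), base = "A1", n_sec = 1200) {
  st <- rep(base, n_sec)
  for (o in overrides) st[o$at] <- o$stage
  stage_sequence(st)
}

# random stage sequence with optional artifact fraction
random_sequence <- function(n_sec, p_artifact = 0) {
  st <- sample(c("0", "A1", "A2", "A3", "B1", "B2/3", "C"), n_sec,
               replace = TRUE)
  art <- stats::runif(n_sec) < p_artifact
  stage_sequence(st, artifact = art)
}

# stage tour: one minute per stage, used for classifier recall checks
tour_course <- function() {
  stage_sequence(rep(c("0", "A1", "A2", "A3", "B1", "B2/3", "C"), each = 60))
}

# shared synthetic calibration profile (computed once per test run)
shared_calib <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      rec <- simulate_calibration_segment(30, seed = 901)
      val <<- calibrate(filter_recording(rec))
    }
    val
  }
})
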