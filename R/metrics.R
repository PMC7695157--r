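# Stage amounts, mean vigilance values, minute-block criteria and the
# arousal stability score (ASS).

# reporting groups: A2 and A3 are classified separately but reported merged
.AMOUNT_GROUPS <- c("0", "A1", "A2/3", "B1", "B2/3", "C")

amount_group <- function(stages) {
  g <- stages
  g[g %in% c("A2", "A3")] <- "A2/3"
  g
}

# indices of full minutes; errors if the sequence is shorter than 1 min
minute_index <- function(n) {
  if (n < 60L) fail("sequence spans %d s; metrics need at least one full minute", n)
  n_min <- n %/% 60L
  rep(seq_len(n_min), each = 60L)[seq_len(n_min * 60L)]
}

#' Percentage stage amounts per minute and for the total recording
#'
#' For each full recording minute and for the whole recording, the share of
#' each reported stage group (0, A1, A2/3, B1, B2/3, C) among the
#' *non-artifact* seconds of that window:
#' `amount * 100 / number of non-artifact seconds`. Windows without any
#' non-artifact second are reported as missing (`NA`), not as zero.
#'
#' @param seq a [stage_sequence()] with at least one non-artifact second.
#' @return A data.frame with one row per minute plus a `"total"` row;
#'   columns `window`, `n_nonartifact`, and one percentage column per stage
#'   group. Percentages in each evaluable row sum to 100.
#' @export
#' @examples
#' s <- stage_sequence(rep(c("A1", "A1", "B2/3"), 20))
#' stage_amounts(s)["total", ]
stage_amounts <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  if (all(seq$artifact)) {
    fail("all seconds are artifact-flagged; stage amounts are undefined")
  }
  n <- length(seq)
  mi <- minute_index(n)
  n_min <- max(mi)
  grp <- amount_group(seq$stages)
  row_of <- function(idx) {
    g <- grp[idx]
    g <- g[!is.na(g)]
    k <- length(g)
    if (k == 0L) {
      return(c(n_nonartifact = 0, stats::setNames(rep(NA_real_, 6), .AMOUNT_GROUPS)))
    }
    counts <- table(factor(g, levels = .AMOUNT_GROUPS))
    c(n_nonartifact = k, as.numeric(counts) * 100 / k)
  }
  rows <- t(vapply(seq_len(n_min), function(m) row_of(which(mi == m)),
                   numeric(7)))
  total <- row_of(seq_len(n_min * 60L))
  out <- as.data.frame(rbind(rows, total))
  names(out) <- c("n_nonartifact", .AMOUNT_GROUPS)
  out <- cbind(window = c(as.character(seq_len(n_min)), "total"), out)
  rownames(out) <- out$window
  out
}

#' Mean vigilance value (MVV) per minute and in total
#'
#' Averages the fixed numeric stage scores (C = 1 ... 0 = 7) over the
#' non-artifact seconds of each full minute and of the whole recording.
#'
#' @param seq a [stage_sequence()] with at least one non-artifact second.
#' @return A list of class `mvv_course` with `per_minute` (numeric vector,
#'   `NA` for minutes without non-artifact seconds) and `total`.
#' @export
#' @examples
#' mean_vigilance_value(stage_sequence(rep("0", 120)))$total
mean_vigilance_value <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  if (all(seq$artifact)) {
    fail("all seconds are artifact-flagged; the mean vigilance value is undefined")
  }
  sc <- stage_scores(seq)
  mi <- minute_index(length(seq))
  per_min <- vapply(seq_len(max(mi)), function(m) {
    v <- sc[mi == m]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(per_minute = per_min,
                 total = mean(sc[seq_len(max(mi) * 60L)], na.rm = TRUE)),
            class = "mvv_course")
}

#' @export
print.mvv_course <- function(x, ...) {
  cat(sprintf("<mvv_course> total MVV %.2f over %d minute(s)\n",
              x$total, length(x$per_minute)))
  invisible(x)
}

#' Per-minute fulfilment of the arousal-stability criteria
#'
#' For every full 1-min block the criteria are evaluated over its
#' non-artifact seconds (inclusive boundaries, integer arithmetic):
#' criterion I: at least 2/3 of seconds in 0/A stages (`crit_I_0A`) or in
#' 0/A1 (`crit_I_0A1`); criterion II: at least 1/3 in B stages (B1 + B2/3);
#' criterion III: at least 1/3 in B2/3; criterion IV: at least one C second.
#' Blocks with fewer than `min_evaluable` non-artifact seconds are marked
#' unevaluable (`NA` criteria).
#'
#' @param seq a [stage_sequence()] spanning at least one full minute.
#' @param min_evaluable minimal non-artifact seconds per evaluable block.
#' @return A data.frame with one row per minute: `minute`, `n_nonartifact`,
#'   `evaluable`, `crit_I_0A`, `crit_I_0A1`, `crit_II`, `crit_III`,
#'   `crit_IV`.
#' @export
minute_criteria <- function(seq, min_evaluable = 20) {
  stopifnot(inherits(seq, "stage_sequence"))
  mi <- minute_index(length(seq))
  n_min <- max(mi)
  out <- data.frame(minute = seq_len(n_min), n_nonartifact = 0L,
                    evaluable = FALSE, crit_I_0A = NA, crit_I_0A1 = NA,
                    crit_II = NA, crit_III = NA, crit_IV = NA)
  for (m in seq_len(n_min)) {
    st <- seq$stages[mi == m]
    st <- st[!is.na(st)]
    k <- length(st)
    out$n_nonartifact[m] <- k
    if (k < min_evaluable) next
    n0a <- sum(st %in% c("0", "A1", "A2", "A3"))
    n0a1 <- sum(st %in% c("0", "A1"))
    nb <- sum(st %in% c("B1", "B2/3"))
    nb23 <- sum(st == "B2/3")
    nc <- sum(st == "C")
    out$evaluable[m] <- TRUE
    out$crit_I_0A[m] <- 3L * n0a >= 2L * k
    out$crit_I_0A1[m] <- 3L * n0a1 >= 2L * k
    out$crit_II[m] <- 3L * nb >= k
    out$crit_III[m] <- 3L * nb23 >= k
    out$crit_IV[m] <- nc >= 1L
  }
  out
}

#' Arousal stability score (ASS)
#'
#' Summarises the speed and depth of the vigilance decline as a single score
#' from 1 (least stable) to 14 (most stable). The recording is divided into
#' four consecutive equal quartiles of minutes (5-min quartiles for the
#' canonical 20-min recording). Writing qII, qIII, qIV for the earliest
#' quartile in which any evaluable minute fulfils criterion II, III or IV
#' (see [minute_criteria()]):
#' * a C stage occurred (criterion IV): score = qIV (1..4),
#' * otherwise B2/3 dominance (criterion III): score = 4 + qIII (5..8),
#' * otherwise B dominance (criterion II): score = 8 + qII (9..12),
#' * otherwise 14 if every evaluable minute fulfils the 0/A1 form of
#'   criterion I (only 0/A1 stages), else 13 (only 0/A stages).
#'
#' Higher scores correspond to higher arousal stability. The interior score
#' bands follow from the printed anchor values (14, 13, 4, 1) and the
#' severity ordering of the criteria; a different band table can be swapped
#' in via `score_table`.
#'
#' @param seq a [stage_sequence()] whose full-minute count is divisible
#'   by 4.
#' @param min_evaluable passed to [minute_criteria()].
#' @param score_table named list with offsets for the criterion bands,
#'   default `list(IV = 0, III = 4, II = 8, none_0A1 = 14, none_0A = 13)`.
#' @return An object of class `ass_result`: `score`, `decisive_criterion`
#'   (`"none"`, `"II"`, `"III"` or `"IV"`), `decisive_quartile` (1..4 or
#'   `NA`), `quartile_of_minute`, and the criteria table.
#' @export
#' @examples
#' arousal_stability_score(stage_sequence(rep("A1", 1200)))$score
arousal_stability_score <- function(seq, min_evaluable = 20,
                                    score_table = list(IV = 0, III = 4,
                                                       II = 8,
                                                       none_0A1 = 14,
                                                       none_0A = 13)) {
  stopifnot(inherits(seq, "stage_sequence"))
  crit <- minute_criteria(seq, min_evaluable = min_evaluable)
  n_min <- nrow(crit)
  if (n_min %% 4L != 0L) {
    fail("ASS needs a minute count divisible into 4 equal quartiles (got %d)",
         n_min)
  }
  q_of <- rep(1:4, each = n_min %/% 4L)
  ev <- crit$evaluable
  if (!any(ev)) fail("no evaluable minutes; ASS is undefined")
  for (q in 1:4) {
    if (!any(ev[q_of == q])) {
      fail("quartile %d has no evaluable minute; ASS is undefined", q)
    }
  }
  first_q <- function(flag) {
    hit <- which(ev & !is.na(flag) & flag)
    if (length(hit) == 0L) NA_integer_ else q_of[min(hit)]
  }
  qIV <- first_q(crit$crit_IV)
  qIII <- first_q(crit$crit_III)
  qII <- first_q(crit$crit_II)
  if (!is.na(qIV)) {
    score <- score_table$IV + qIV; decisive <- "IV"; dq <- qIV
  } else if (!is.na(qIII)) {
    score <- score_table$III + qIII; decisive <- "III"; dq <- qIII
  } else if (!is.na(qII)) {
    score <- score_table$II + qII; decisive <- "II"; dq <- qII
  } else {
    only_0a1 <- all(crit$crit_I_0A1[ev])
    score <- if (only_0a1) score_table$none_0A1 else score_table$none_0A
    decisive <- "none"; dq <- NA_integer_
  }
  structure(list(score = as.integer(score), decisive_criterion = decisive,
                 decisive_quartile = dq, quartile_of_minute = q_of,
                 criteria = crit),
            class = "ass_result")
}

#' @export
print.ass_result <- function(x, ...) {
  cat(sprintf("<ass_result> ASS = %d (decisive criterion %s%s)\n",
              x$score, x$decisive_criterion,
              if (is.na(x$decisive_quartile)) "" else
                sprintf(", quartile %d", x$decisive_quartile)))
  invisible(x)
}

#' Per-subject vigilance summary
#'
#' Convenience wrapper computing amounts, MVV course, ASS and the C-second
#' count of one stage sequence, as consumed by the cohort layer.
#'
#' @param seq a [stage_sequence()].
#' @param min_evaluable passed to [arousal_stability_score()].
#' @return A list with `ass` (the `ass_result`), `mvv` (the `mvv_course`),
#'   `amounts` and `c_count`.
#' @export
summarize_vigilance <- function(seq, min_evaluable = 20) {
  list(ass = arousal_stability_score(seq, min_evaluable = min_evaluable),
       mvv = mean_vigilance_value(seq),
       amounts = stage_amounts(seq),
       c_count = sum(!is.na(seq$stages) & seq$stages == "C"))
}
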