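# End-to-end cohort analysis driver: simulate (or load) a cohort, compute
# per-subject vigilance metrics and prototype assignments, and run the
# group-level statistics.

#' Run the full cohort analysis pipeline
#'
#' Reproduces the analysis sequence for a two-group resting-state cohort:
#' per-subject ASS/MVV/amounts, 3- and 4-prototype assignment, one-tailed
#' Mann-Whitney U on the ASS (directed hypothesis: patients more stable),
#' two-tailed t test on C-second counts, chi-square tests on the prototype
#' distributions, a median split of the patients by sleep efficiency with
#' subgroup-versus-control comparisons, and per-(sub)group Spearman
#' correlations of the ASS with sleep and psychometric covariates
#' (one-sided for the directed sleep-continuity hypotheses).
#'
#' @param config a list, or path to a YAML file, with entries `seed`
#'   (default 1), `cohort` (arguments for [cohort_spec()]) and optionally
#'   `output` (directory for `report.json` / `report.md`).
#' @return A list of class `vig_report`; identical (byte-identical JSON)
#'   across reruns with the same config.
#' @export
#' @examples
#' rep <- run_pipeline(list(seed = 7,
#'                          cohort = list(n_patients = 6, n_controls = 5)))
#' rep$group_tests$ass_mann_whitney$p_value
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) fail("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0L) {
    fail("config must be a non-empty list or a YAML file path")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
  cohort <- simulate_cohort(spec)
  subj <- cohort$subjects
  pat <- subj$group == "patient"

  # prototype assignment from the per-minute MVV courses
  assign_all <- function(model) {
    pr <- build_prototypes(model, duration_min = spec$duration_min)
    vapply(seq_len(nrow(subj)), function(i) {
      assign_prototype(cohort$mvv_courses[i, ], pr)$label
    }, character(1))
  }
  subj$prototype3 <- tryCatch(assign_all("three"), error = function(e) NA)
  subj$prototype4 <- tryCatch(assign_all("four"), error = function(e) NA)

  tab3 <- prototype_distribution(subj$prototype3, subj$group)
  tab4 <- prototype_distribution(subj$prototype4, subj$group)
  drop0 <- function(tab) tab[, colSums(tab) > 0, drop = FALSE]

  group_tests <- list(
    ass_mann_whitney = mann_whitney_u(subj$ass[pat], subj$ass[!pat],
                                      tail = "greater"),
    c_count_t_test = {
      tt <- t.test(subj$c_count[pat], subj$c_count[!pat])
      vig_test("Welch t test", statistic = c(t = unname(tt$statistic)),
               p_value = tt$p.value, tail = "two",
               n = c(n_a = sum(pat), n_b = sum(!pat)),
               df = unname(tt$parameter), exact = FALSE,
               estimate = c(mean_a = unname(tt$estimate[1]),
                            mean_b = unname(tt$estimate[2])))
    },
    prototype3_chisq = chi_square_independence(drop0(tab3), tail = "one"),
    prototype4_chisq = chi_square_independence(drop0(tab4), tail = "one")
  )

  # ASS-covariate correlations per group; sleep-continuity hypotheses are
  # directed (lower sleep efficiency / higher arousal index with higher ASS)
  cor_block <- function(rows) {
    directed <- c(sleep_efficiency = "less", arousal_index = "greater")
    lapply(stats::setNames(nm = cohort$spec$covariates$name), function(cv) {
      tail <- if (cv %in% names(directed)) directed[[cv]] else "two"
      tryCatch(as_list_vig_test(
        spearman_test(subj$ass[rows], subj[[cv]][rows], tail = tail)),
        error = function(e) list(error = conditionMessage(e)))
    })
  }

  # insomnia subgroups by median split of sleep efficiency
  ms <- median_split(subj$sleep_efficiency[pat])
  pat_idx <- which(pat)
  low_idx <- pat_idx[ms$low]
  high_idx <- pat_idx[ms$high]
  subgroups <- list(
    threshold = ms$threshold,
    n_low = length(low_idx), n_high = length(high_idx),
    ass_low_vs_controls = as_list_vig_test(
      mann_whitney_u(subj$ass[low_idx], subj$ass[!pat], tail = "greater")),
    ass_high_vs_controls = as_list_vig_test(
      mann_whitney_u(subj$ass[high_idx], subj$ass[!pat], tail = "greater")),
    correlations_low = cor_block(low_idx),
    correlations_high = cor_block(high_idx)
  )

  amounts_mean <- function(rows) {
    m <- vapply(rows, function(i) {
      a <- stage_amounts(cohort$courses[[i]])
      unlist(a["total", .AMOUNT_GROUPS])
    }, numeric(length(.AMOUNT_GROUPS)))
    rowMeans(m)
  }

  report <- list(
    meta = list(package = "vigistate", seed = seed,
                n_patients = spec$n_patients, n_controls = spec$n_controls,
                duration_min = spec$duration_min),
    group_tests = group_tests,
    prototype_tables = list(three = as.data.frame.matrix(tab3),
                            four = as.data.frame.matrix(tab4)),
    subgroups = subgroups,
    correlations = list(patients = cor_block(which(pat)),
                        controls = cor_block(which(!pat))),
    mean_total_amounts = list(patients = as.list(amounts_mean(which(pat))),
                              controls = as.list(amounts_mean(which(!pat)))),
    subjects = subj
  )
  class(report) <- "vig_report"

  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_json(report), file.path(config$output, "report.json"))
    writeLines(format_report(report), file.path(config$output, "report.md"))
    write_cohort_table(cohort, file.path(config$output, "subjects.tsv"))
  }
  report
}

# JSON serialization of a report (deterministic for fixed config)
report_json <- function(report) {
  r <- unclass(report)
  r$group_tests <- lapply(r$group_tests, as_list_vig_test)
  jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                   pretty = TRUE, na = "null")
}

#' @export
print.vig_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable markdown summary of a pipeline report
#'
#' @param report a [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "vig_report"))
  fmt_t <- function(t) {
    sprintf("%s = %.4g, p = %.4g (%s-tailed)",
            names(t$statistic)[1], t$statistic[1], t$p_value, t$tail)
  }
  gt <- report$group_tests
  c("# Cohort vigilance report",
    sprintf("Patients n = %d, controls n = %d, %g-min recordings (seed %d)",
            report$meta$n_patients, report$meta$n_controls,
            report$meta$duration_min, report$meta$seed),
    "",
    "## Group comparisons",
    sprintf("- Arousal stability score (Mann-Whitney): %s",
            fmt_t(gt$ass_mann_whitney)),
    sprintf("- C-second count (Welch t): %s", fmt_t(gt$c_count_t_test)),
    sprintf("- 3-prototype distribution (chi-square): %s",
            fmt_t(gt$prototype3_chisq)),
    sprintf("- 4-prototype distribution (chi-square): %s",
            fmt_t(gt$prototype4_chisq)),
    "",
    "## Patient subgroups (median split at sleep efficiency)",
    sprintf("- threshold = %.1f%%, n = %d / %d", report$subgroups$threshold,
            report$subgroups$n_low, report$subgroups$n_high),
    sprintf("- ASS high-SE vs controls: U = %.4g, p = %.4g (one-tailed)",
            report$subgroups$ass_high_vs_controls$U,
            report$subgroups$ass_high_vs_controls$p_value),
    sprintf("- ASS low-SE vs controls: U = %.4g, p = %.4g (one-tailed)",
            report$subgroups$ass_low_vs_controls$U,
            report$subgroups$ass_low_vs_controls$p_value))
}
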