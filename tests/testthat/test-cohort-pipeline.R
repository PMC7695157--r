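# synthetic cohorts and the end-to-end analysis driver

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(n_patients = 0), "positive integer")
  expect_error(cohort_spec(patient_mix = c(adaptive = 0.7, unstable = 0.1,
                                           stable = 0.1, hyperstable = 0.2)),
               "summing to 1")
  expect_error(cohort_spec(duration_min = 2), "duration_min")
  expect_warning(covariate_model(data.frame(name = "isi", intercept = 3,
                                            slope_ass = 1, patient_shift = 0,
                                            sd = 0, lo = 0, hi = 28)),
                 "degenerate")
})

test_that("cohorts are reproducible and record ground truth", {
  spec <- cohort_spec(n_patients = 8, n_controls = 6, seed = 11)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_equal(nrow(a$subjects), 14)
  expect_true(all(a$subjects$regulation_type %in% regulation_types()))
  expect_true(all(a$subjects$ass %in% 1:14))
  expect_true(all(a$subjects$sleep_efficiency >= 25 &
                    a$subjects$sleep_efficiency <= 100))
  expect_length(a$courses, 14)
  expect_equal(dim(a$mvv_courses), c(14, 20))
})

test_that("a zero-slope covariate stays inside the permutation null band", {
  # isi has slope 0 on the ASS by default
  coh <- simulate_cohort(cohort_spec(n_patients = 30, n_controls = 1,
                                     seed = 12))
  s <- coh$subjects[coh$subjects$group == "patient", ]
  rho <- spearman_test(s$ass, s$isi)$statistic[["rho"]]
  set.seed(13)
  null_rho <- replicate(2000, cor(rank(s$ass), rank(sample(s$isi))))
  band <- quantile(null_rho, c(0.025, 0.975))
  expect_gt(rho, band[1])
  expect_lt(rho, band[2])
})

test_that("the planted ASS-sleep-efficiency slope is recoverable at n = 17", {
  hits <- vapply(1:200, function(r) {
    coh <- simulate_cohort(cohort_spec(n_patients = 17, n_controls = 1,
                                       seed = 20000 + r))
    s <- coh$subjects[coh$subjects$group == "patient", ]
    p <- spearman_test(s$ass, s$sleep_efficiency, tail = "less")$p_value
    p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the pipeline report is structurally complete and deterministic", {
  cfg <- list(seed = 5, cohort = list(n_patients = 12, n_controls = 10))
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "vig_report")
  gt <- rep1$group_tests
  expect_named(gt, c("ass_mann_whitney", "c_count_t_test",
                     "prototype3_chisq", "prototype4_chisq"))
  expect_equal(gt$ass_mann_whitney$tail, "greater")
  expect_equal(gt$c_count_t_test$tail, "two")
  expect_true(all(c("threshold", "ass_low_vs_controls",
                    "ass_high_vs_controls") %in% names(rep1$subgroups)))
  expect_true("sleep_efficiency" %in% names(rep1$correlations$patients))
  expect_equal(nrow(rep1$subjects), 22)
  # rerun with the same config: byte-identical JSON
  rep2 <- run_pipeline(cfg)
  expect_identical(vigistate:::report_json(rep1),
                   vigistate:::report_json(rep2))
  expect_error(run_pipeline(list()), "non-empty")
})

test_that("the pipeline reads YAML configs and writes its outputs", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "cohort.yaml")
  writeLines(c("seed: 9",
               "cohort:",
               "  n_patients: 6",
               "  n_controls: 5",
               sprintf("output: %s", file.path(out, "res"))), cfgfile)
  rep <- run_pipeline(cfgfile)
  expect_equal(rep$meta$n_patients, 6)
  expect_true(file.exists(file.path(out, "res", "report.json")))
  expect_true(file.exists(file.path(out, "res", "report.md")))
  expect_true(file.exists(file.path(out, "res", "subjects.tsv")))
  parsed <- jsonlite::read_json(file.path(out, "res", "report.json"))
  expect_equal(parsed$meta$seed, 9)
})

test_that("ground-truth regulation orders median ASS as expected", {
  med <- vapply(c("hyperstable", "adaptive", "unstable"), function(tp) {
    median(vapply(1:30, function(s) {
      arousal_stability_score(
        simulate_stage_course(tp, duration_min = 20,
                              seed = split_seed(77, s)))$score
    }, numeric(1)))
  }, numeric(1))
  expect_gt(med[["hyperstable"]], med[["adaptive"]])
  expect_gt(med[["adaptive"]], med[["unstable"]])
})
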