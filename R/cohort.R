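# Synthetic cohorts: regulation-type mixtures per group, per-subject stage
# courses, and covariates generated from a linear model on the realized
# arousal stability score.

#' Linear covariate model of a synthetic cohort
#'
#' Each covariate is generated as
#' `intercept + slope_ass * ASS + patient_shift * [patient] + Normal(0, sd)`,
#' then clamped to `[lo, hi]`. The defaults emulate the structure of an
#' insomnia-versus-control cohort: polysomnographic sleep-continuity
#' measures are coupled to the arousal stability score (lower sleep
#' efficiency, more wake after sleep onset and a higher arousal index in
#' subjects with a more stable daytime arousal regulation), while the
#' psychometric scales differ between groups but are unrelated to the ASS.
#'
#' @param overrides optional data.frame (same columns) replacing rows by
#'   `name`.
#' @return A data.frame with columns `name`, `intercept`, `slope_ass`,
#'   `patient_shift`, `sd`, `lo`, `hi`.
#' @export
covariate_model <- function(overrides = NULL) {
  m <- utils::read.csv(text = "name,intercept,slope_ass,patient_shift,sd,lo,hi
sleep_efficiency,97,-2.3,0,10,25,100
arousal_index,6,0.75,0,4,0,60
waso,10,5,15,25,0,400
total_sleep_time,420,-7,-20,30,120,480
isi,3,0,14.5,4,0,28
psqi,4.3,0,7.6,3,0,21
bdi,1.2,0,2,2.5,0,30
psrs23,16.7,0,8.9,7,0,69
aps,28.4,0,5.5,5,12,60
psas_cognitive,9.5,0,5,4,7,35
psas_somatic,8.8,0,3.3,3,8,40
mcqi,98.4,0,24.9,25,65,260
kss_pre,3.5,0,1.8,1.8,1,9
kss_post,4.7,0,0.6,2,1,9", stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$name[i], m$name)
      if (is.na(j)) m <- rbind(m, overrides[i, names(m)])
      else m[j, ] <- overrides[i, names(m)]
    }
  }
  if (any(m$sd < 0)) fail("covariate noise SDs must be non-negative")
  if (any(m$sd == 0 & (m$slope_ass != 0 | m$patient_shift != 0))) {
    warning("degenerate covariate model: zero noise with non-zero coefficients")
  }
  m
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_patients,n_controls subjects per group (>= 1).
#' @param patient_mix,control_mix probability vectors over
#'   [regulation_types()]; must sum to 1. The defaults enrich the patient
#'   group in stable/hyperstable regulation and the control group in
#'   adaptive/unstable regulation.
#' @param duration_min recording length in minutes (>= 4).
#' @param covariates a [covariate_model()].
#' @param seed global cohort seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 34, n_controls = 25,
                        patient_mix = c(adaptive = 0.20, unstable = 0.10,
                                        stable = 0.40, hyperstable = 0.30),
                        control_mix = c(adaptive = 0.55, unstable = 0.25,
                                        stable = 0.15, hyperstable = 0.05),
                        duration_min = 20,
                        covariates = covariate_model(), seed = 1) {
  for (nm in c("n_patients", "n_controls")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1 || v != round(v)) {
      fail("%s must be a positive integer (got %s)", nm, format(v))
    }
  }
  check_mix <- function(mix, nm) {
    if (!all(regulation_types() %in% names(mix))) {
      fail("%s must be named over: %s", nm,
           paste(regulation_types(), collapse = ", "))
    }
    mix <- mix[regulation_types()]
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      fail("%s must be a probability vector summing to 1", nm)
    }
    mix
  }
  if (!is.numeric(duration_min) || duration_min < 4) {
    fail("duration_min must be >= 4 minutes")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 patient_mix = check_mix(patient_mix, "patient_mix"),
                 control_mix = check_mix(control_mix, "control_mix"),
                 duration_min = duration_min,
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-group cohort with known ground truth
#'
#' For every subject: a regulation type is drawn from the group mixture, a
#' stage course is simulated ([simulate_stage_course()]), the vigilance
#' metrics are computed from the course, and covariates are generated from
#' the linear model on the realized ASS. All randomness derives from the
#' cohort seed via [split_seed()]; a fixed seed yields a bit-identical
#' cohort.
#'
#' @param spec a [cohort_spec()].
#' @param signals also synthesize raw recordings (slow; default `FALSE`).
#' @return A list of class `vig_cohort`: `subjects` (one row per subject:
#'   id, group, ground-truth `regulation_type`, `ass`, `mvv_total`,
#'   `c_count`, covariates), `courses` (list of [stage_sequence()]),
#'   `mvv_courses` (per-minute matrix), optional `simulations`, and `spec`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_patients = 3, n_controls = 2))
#' coh$subjects[, c("group", "regulation_type", "ass")]
simulate_cohort <- function(spec, signals = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_patients + spec$n_controls
  group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  courses <- vector("list", n_tot)
  sims <- if (signals) vector("list", n_tot) else NULL
  mvv_mat <- matrix(NA_real_, n_tot, spec$duration_min)
  rows <- vector("list", n_tot)
  cm <- spec$covariates
  for (i in seq_len(n_tot)) {
    s_type <- split_seed(spec$seed, 4L * i)
    s_course <- split_seed(spec$seed, 4L * i + 1L)
    s_cov <- split_seed(spec$seed, 4L * i + 2L)
    mix <- if (group[i] == "patient") spec$patient_mix else spec$control_mix
    rt <- with_seed(s_type, sample(names(mix), 1, prob = mix))
    course <- simulate_stage_course(rt, duration_min = spec$duration_min,
                                    seed = s_course)
    courses[[i]] <- course
    if (signals) {
      sims[[i]] <- simulate_recording(course,
                                      seed = split_seed(spec$seed, 4L * i + 3L))
    }
    vs <- summarize_vigilance(course)
    mvv_mat[i, ] <- vs$mvv$per_minute
    ass <- vs$ass$score
    cov_vals <- with_seed(s_cov, {
      v <- cm$intercept + cm$slope_ass * ass +
        cm$patient_shift * (group[i] == "patient") +
        rnorm(nrow(cm), 0, cm$sd)
      round(clamp(v, cm$lo, cm$hi), 1)
    })
    names(cov_vals) <- cm$name
    rows[[i]] <- c(list(subject_id = sprintf("S%03d", i), group = group[i],
                        regulation_type = rt, ass = ass,
                        mvv_total = vs$mvv$total, c_count = vs$c_count),
                   as.list(cov_vals))
  }
  subjects <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(list(subjects = subjects, courses = courses,
                 mvv_courses = mvv_mat, simulations = sims, spec = spec),
            class = "vig_cohort")
}

#' @export
print.vig_cohort <- function(x, ...) {
  cat(sprintf("<vig_cohort> %d patients + %d controls, %g min each\n",
              x$spec$n_patients, x$spec$n_controls, x$spec$duration_min))
  print(table(x$subjects$group, x$subjects$regulation_type))
  invisible(x)
}

#' Write the per-subject cohort table as tab-separated text
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "vig_cohort"))
  utils::write.table(cohort$subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
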