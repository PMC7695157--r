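# Synthetic vigilance-stage trajectories.
#
# Stage courses are simulated as a minute-level Markov chain on the 7-stage
# ladder and then expanded to seconds with dwell jitter. The chain realizes
# the four verbal regulation prototypes: adaptive (graduated decline),
# unstable (accelerated decline), stable (no decline below the A band) and
# hyperstable (retention in 0/A1).

#' The four arousal-regulation types
#'
#' @return Character vector of the four regulation labels.
#' @export
regulation_types <- function() {
  c("adaptive", "unstable", "stable", "hyperstable")
}

#' Transition parameters of the minute-level stage chain
#'
#' Each regulation type maps to one parameterisation of a birth-death chain
#' on the vigilance scores 7 (stage 0) down to 1 (stage C). Per minute the
#' chain descends `step_down` levels with probability `p_down` (never below
#' `floor_score`), ascends one level with probability `p_up`, enters C from
#' B2/3 with probability `p_c_entry` and leaves C with probability
#' `p_c_exit`. `dwell_noise` is the per-second probability of a one-level
#' excursion during second-level expansion; `dwell_max_shift` bounds the
#' random changeover delay (seconds) at minute boundaries.
#'
#' Type defaults: the hyperstable chain is confined to scores 6..7 (stages
#' A1/0, descent pressure effectively zero), the stable chain to 4..7 (no B
#' or C reachable), while adaptive and unstable chains may descend to B2/3
#' and enter C; the unstable chain descends two levels per minute.
#'
#' @param type one of [regulation_types()], or `NULL` for fully manual
#'   parameters.
#' @param p_down,p_up,p_c_entry,p_c_exit transition probabilities in `[0,1]`.
#' @param floor_score lowest reachable wake score (2 = B2/3).
#' @param start_score score of the first minute (7 = activated stage 0).
#' @param step_down levels descended per downward transition.
#' @param dwell_noise per-second excursion probability in the expansion.
#' @param dwell_max_shift maximal changeover delay at minute boundaries (s).
#' @param c_events_mean mean number of extra C seconds planted in a C minute
#'   beyond the guaranteed one.
#' @return An object of class `stage_course_params`.
#' @export
#' @examples
#' stage_course_params("hyperstable")
stage_course_params <- function(type = NULL,
                                p_down = NULL, p_up = NULL,
                                p_c_entry = NULL, p_c_exit = 0.5,
                                floor_score = NULL, start_score = NULL,
                                step_down = NULL,
                                dwell_noise = 0.08, dwell_max_shift = 20,
                                c_events_mean = 1) {
  defaults <- list(
    adaptive    = list(p_down = 0.35, p_up = 0.02, p_c_entry = 0.25,
                       floor_score = 2, start_score = 7, step_down = 1),
    unstable    = list(p_down = 0.92, p_up = 0.02, p_c_entry = 0.35,
                       floor_score = 2, start_score = 7, step_down = 2),
    stable      = list(p_down = 0.15, p_up = 0.05, p_c_entry = 0,
                       floor_score = 4, start_score = 5, step_down = 1),
    hyperstable = list(p_down = 0.15, p_up = 0.25, p_c_entry = 0,
                       floor_score = 6, start_score = 7, step_down = 1)
  )
  if (!is.null(type)) {
    if (!is.character(type) || length(type) != 1L ||
        !type %in% regulation_types()) {
      fail("unknown regulation type '%s'; expected one of: %s",
           paste(type, collapse = ","),
           paste(regulation_types(), collapse = ", "))
    }
    d <- defaults[[type]]
  } else {
    d <- list()
  }
  pick <- function(x, nm) if (!is.null(x)) x else d[[nm]]
  p <- list(type = if (is.null(type)) NA_character_ else type,
            p_down = pick(p_down, "p_down"),
            p_up = pick(p_up, "p_up"),
            p_c_entry = pick(p_c_entry, "p_c_entry"),
            p_c_exit = p_c_exit,
            floor_score = pick(floor_score, "floor_score"),
            start_score = pick(start_score, "start_score"),
            step_down = pick(step_down, "step_down"),
            dwell_noise = dwell_noise,
            dwell_max_shift = as.integer(dwell_max_shift),
            c_events_mean = c_events_mean)
  for (nm in c("p_down", "p_up", "p_c_entry", "p_c_exit", "dwell_noise")) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      fail("parameter '%s' must be a probability in [0,1]", nm)
    }
  }
  if (is.null(p$floor_score) || p$floor_score < 2 || p$floor_score > 7) {
    fail("floor_score must lie in 2..7")
  }
  if (p$start_score < p$floor_score || p$start_score > 7) {
    fail("start_score must lie in floor_score..7")
  }
  if (identical(type, "hyperstable") && p$floor_score < 6) {
    fail("the hyperstable type is confined to stages 0/A1 (floor_score >= 6)")
  }
  class(p) <- "stage_course_params"
  p
}

#' Minute-level transition matrix of the stage chain
#'
#' Exposes the exact Markov chain that [simulate_stage_course()] samples
#' from, so first-passage probabilities (e.g. of the first C minute) can be
#' computed by enumeration and compared with simulated courses.
#'
#' @param params a [stage_course_params()].
#' @return A 7x7 row-stochastic matrix; rows/columns are named by the stage
#'   scores `"1"` (C) to `"7"` (stage 0).
#' @export
build_stage_chain <- function(params) {
  stopifnot(inherits(params, "stage_course_params"))
  P <- matrix(0, 7, 7, dimnames = list(as.character(1:7), as.character(1:7)))
  fl <- params$floor_score
  for (s in 3:7) {
    if (s < fl) { P[s, s] <- 1; next }  # unreachable below the floor
    down <- if (s > fl) params$p_down else 0
    up <- if (s < 7) params$p_up else 0
    tgt <- max(s - params$step_down, fl)
    P[s, tgt] <- P[s, tgt] + down
    if (up > 0) P[s, s + 1] <- up
    P[s, s] <- P[s, s] + 1 - down - up
  }
  if (fl <= 2) {
    P[2, 1] <- params$p_c_entry
    P[2, 3] <- params$p_up
    P[2, 2] <- 1 - params$p_c_entry - params$p_up
  } else {
    P[2, 2] <- 1
  }
  P[1, 2] <- params$p_c_exit
  P[1, 1] <- 1 - params$p_c_exit
  P
}

# sample the minute-level chain
sample_minute_chain <- function(params, n_min) {
  P <- build_stage_chain(params)
  s <- integer(n_min)
  s[1] <- params$start_score
  for (m in seq_len(n_min)[-1]) {
    s[m] <- sample.int(7, 1, prob = P[s[m - 1], ])
  }
  s
}

#' Simulate a per-second vigilance stage course
#'
#' Samples the minute-level chain for the requested regulation type and
#' expands it to seconds: each minute carries its chain stage, minute
#' changeovers are delayed by a random 0..`dwell_max_shift` seconds, wake
#' seconds (score >= 3) make one-level excursions with probability
#' `dwell_noise` (clamped so that no type leaves its admissible stage set and
#' no C second arises outside a chain C minute), and every chain C minute
#' contains at least one C second (sleep-onset events are second-scale; the
#' remaining seconds of a C minute are B2/3 background).
#'
#' @param reg_type one of [regulation_types()].
#' @param params a [stage_course_params()]; defaults to the type defaults.
#' @param duration_min recording length in minutes (>= 4).
#' @param seed integer seed; fixed seed gives a bit-identical course.
#' @return A [stage_sequence()] of `duration_min * 60` seconds with an
#'   all-false artifact mask. Attributes `minute_scores` (the chain states)
#'   and `regulation_type` record the ground truth.
#' @export
#' @examples
#' course <- simulate_stage_course("hyperstable", duration_min = 20, seed = 1)
#' unique(course$stages)
simulate_stage_course <- function(reg_type,
                                  params = stage_course_params(reg_type),
                                  duration_min = 20, seed = 1) {
  if (!is.character(reg_type) || length(reg_type) != 1L ||
      !reg_type %in% regulation_types()) {
    fail("unknown regulation type '%s'; expected one of: %s",
         paste(reg_type, collapse = ","),
         paste(regulation_types(), collapse = ", "))
  }
  stopifnot(inherits(params, "stage_course_params"))
  if (!is.numeric(duration_min) || duration_min < 4 ||
      duration_min != round(duration_min)) {
    fail("duration_min must be an integer >= 4 (got %s)",
         format(duration_min))
  }
  n_min <- as.integer(duration_min)
  with_seed(seed, {
    ms <- sample_minute_chain(params, n_min)
    jitter_floor <- max(params$floor_score, 3L)  # excursions never create B2/3
    secs <- integer(n_min * 60L)
    for (m in seq_len(n_min)) {
      s <- ms[m]
      bg <- if (s == 1L) 2L else s  # C minutes sit on B2/3 background
      block <- rep(bg, 60L)
      shift <- 0L
      if (m > 1L) {
        prev <- ms[m - 1L]
        prev_bg <- if (prev == 1L) 2L else prev
        if (prev_bg != bg && params$dwell_max_shift > 0L) {
          shift <- sample.int(params$dwell_max_shift + 1L, 1L) - 1L
          if (shift > 0L) block[seq_len(shift)] <- prev_bg
        }
      }
      if (s == 1L) {
        n_ev <- 1L + rbinom(1L, 3L, min(1, params$c_events_mean / 3))
        free <- seq.int(shift + 1L, 60L)
        pos <- if (length(free) == 1L) free else
          sample(free, min(n_ev, length(free)))
        block[pos] <- 1L
      }
      idx <- (m - 1L) * 60L + seq_len(60L)
      secs[idx] <- block
    }
    wake <- secs >= 3L
    flip <- wake & runif(length(secs)) < params$dwell_noise
    if (any(flip)) {
      delta <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
      secs[flip] <- clamp(secs[flip] + delta, jitter_floor, 7L)
    }
    out <- stage_sequence(score_stage(secs))
    attr(out, "minute_scores") <- ms
    attr(out, "regulation_type") <- reg_type
    out
  })
}
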