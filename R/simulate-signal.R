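# Stage-locked multichannel EEG/EOG synthesis.
#
# Signal recipe: per-channel 1/f-like background plus stage-gated
# components — narrowband alpha (region-weighted, A stages), 2-7 Hz
# theta/delta noise (B2/3 and C background), spindle/K-complex events
# (C seconds, with emitted markers) and anti-phase slow half-waves on the
# EOG pair (B1 runs). Amplitudes are expressed relative to the posterior
# A1 alpha reference so that calibration-derived thresholds separate the
# stages by construction.

#' Amplitude and shape parameters of the signal synthesizer
#'
#' All RMS amplitudes in microvolts. `alpha_rel` holds the per-stage alpha
#' band power of the anterior/posterior ROIs relative to the posterior A1
#' reference (`alpha_ref_rms^2`): the A1/A2/A3 progression of increasing
#' frontalization with decreasing posterior amplitude.
#'
#' @param alpha_ref_rms posterior A1 alpha RMS (default 10).
#' @param bg_white_rms,bg_slow_rms background mixture components.
#' @param slow_rel_power B2/3 slow-wave power relative to the alpha
#'   reference power (default 1.8).
#' @param alpha_env_sd log-SD of the common per-second alpha
#'   waxing/waning envelope.
#' @param spindle_amp,k_amp event peak amplitudes.
#' @param sem_amp_range SEM peak amplitude range (half of peak-to-peak).
#' @param sem_freq_range SEM frequency range in Hz.
#' @param eog_bg_rms EOG background RMS.
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(alpha_ref_rms = 10, bg_white_rms = 3,
                          bg_slow_rms = 4, slow_rel_power = 1.8,
                          alpha_env_sd = 0.15, spindle_amp = 15, k_amp = 40,
                          sem_amp_range = c(50, 150),
                          sem_freq_range = c(0.2, 0.4), eog_bg_rms = 8) {
  structure(list(alpha_ref_rms = alpha_ref_rms, bg_white_rms = bg_white_rms,
                 bg_slow_rms = bg_slow_rms, slow_rel_power = slow_rel_power,
                 alpha_env_sd = alpha_env_sd, spindle_amp = spindle_amp,
                 k_amp = k_amp, sem_amp_range = sem_amp_range,
                 sem_freq_range = sem_freq_range, eog_bg_rms = eog_bg_rms,
                 # relative alpha power (anterior, posterior) per A stage
                 alpha_rel = list(A1 = c(anterior = 0.15, posterior = 1.00),
                                  A2 = c(anterior = 0.60, posterior = 0.85),
                                  A3 = c(anterior = 0.50, posterior = 0.23))),
            class = "signal_params")
}

# normalise a vector to unit RMS (guarding against all-zero input)
unit_rms <- function(x) {
  s <- sqrt(mean(x^2))
  if (s == 0) x else x / s
}

#' Synthesize a multichannel recording from a stage course
#'
#' Every second's spectral content is locked to its planted stage: A
#' epochs carry narrowband ~10 Hz activity whose anterior/posterior power
#' ratio encodes the sub-stage, B2/3 epochs are theta/delta dominated,
#' B1 runs add anti-phase slow half-waves on the EOG pair, stage 0 epochs
#' are low-voltage background, and every C second receives one spindle or
#' K-complex whose onset is emitted as a marker.
#'
#' @param course a [stage_sequence()] (artifact seconds are synthesized as
#'   background).
#' @param layout channel labels; must contain anterior and posterior EEG
#'   channels and an EOG pair (labels containing `"EOG"`).
#' @param fs integer sampling rate in Hz (default 200).
#' @param seed integer seed.
#' @param params a [signal_params()].
#' @return A list of class `vig_simulation`: `recording` (a [recording()]),
#'   `markers` (data.frame `sample_index`, `marker_type`) and `course`.
#' @export
#' @examples
#' sim <- simulate_recording(stage_sequence(rep("A1", 12)), seed = 1)
#' sim$recording
simulate_recording <- function(course, layout = default_layout(), fs = 200,
                               seed = 1, params = signal_params()) {
  stopifnot(inherits(course, "stage_sequence"))
  if (!is.numeric(fs) || fs != round(fs) || fs < 100) {
    fail("sampling rate must be an integer >= 100 Hz (got %s)", format(fs))
  }
  fs <- as.integer(fs)
  eog <- grep("EOG", layout, value = TRUE)
  if (length(eog) < 2L) fail("layout lacks a horizontal EOG pair")
  eog <- eog[1:2]
  rois <- default_rois(layout)
  if (length(rois$anterior) == 0L || length(rois$posterior) == 0L) {
    fail("layout must include anterior and posterior EEG channels")
  }
  n_sec <- length(course)
  n <- n_sec * fs
  nyq <- fs / 2
  stages <- course$stages
  stages[is.na(stages)] <- "0"  # artifact seconds synthesized as background
  with_seed(seed, {
    n_ch <- length(layout)
    samples <- matrix(0, n_ch, n, dimnames = list(layout, NULL))
    bf_slowbg <- signal::butter(1, 7 / nyq, "low")
    bf_theta <- signal::butter(2, c(2, 7) / nyq, "pass")
    t_idx <- seq_len(n) / fs
    # common alpha waxing/waning envelope, per second
    env <- rep(exp(rnorm(n_sec, 0, params$alpha_env_sd)), each = fs)
    # per-second alpha gain by region (RMS scale)
    region_of <- function(ch) {
      if (ch %in% rois$anterior) "anterior"
      else if (ch %in% rois$posterior) "posterior"
      else "central"
    }
    rel_gain <- function(stage, region) {
      rel <- params$alpha_rel[[stage]]
      if (is.null(rel)) return(0)
      if (region == "central") mean(rel) * 0.5 else unname(rel[region])
    }
    slow_gain_sec <- ifelse(stages %in% c("B2/3", "C"),
                            sqrt(params$slow_rel_power) * params$alpha_ref_rms,
                            0)
    slow_gain <- rep(slow_gain_sec, each = fs)
    for (ci in seq_len(n_ch)) {
      ch <- layout[ci]
      is_eog <- ch %in% eog
      bg_rms <- if (is_eog) params$eog_bg_rms else params$bg_white_rms
      x <- rnorm(n, 0, bg_rms) +
        params$bg_slow_rms * unit_rms(signal::filtfilt(bf_slowbg, rnorm(n)))
      if (!is_eog) {
        reg <- region_of(ch)
        gain_sec <- vapply(stages, function(s) rel_gain(s, reg), numeric(1))
        if (any(gain_sec > 0)) {
          f_c <- clamp(rnorm(1, 10, 0.4), 8.5, 11.5)
          tone <- sqrt(2) * sin(2 * pi * f_c * t_idx + runif(1, 0, 2 * pi))
          x <- x + tone * env * rep(sqrt(gain_sec), each = fs) *
            params$alpha_ref_rms
        }
        x <- x + slow_gain * unit_rms(signal::filtfilt(bf_theta, rnorm(n)))
      }
      samples[ci, ] <- x
    }
    # sleep-onset events on C seconds, one marker per C second
    markers <- list()
    central <- intersect(c("C3", "Cz", "C4", "F3", "Fz", "F4"), layout)
    if (length(central) == 0L) central <- setdiff(layout, eog)
    c_secs <- which(stages == "C")
    for (s in c_secs) {
      type <- sample(c("spindle", "kcomplex"), 1, prob = c(0.6, 0.4))
      onset <- (s - 1L) * fs + sample.int(fs %/% 2, 1)
      if (type == "spindle") {
        dur <- round(runif(1, 0.5, 1) * fs)
        k <- seq_len(dur)
        wave <- params$spindle_amp * sin(2 * pi * 13.5 * k / fs) *
          (0.5 - 0.5 * cos(2 * pi * k / dur))
      } else {
        dur <- round(0.8 * fs)
        k <- seq_len(dur)
        wave <- params$k_amp * -sin(2 * pi * k / dur) *
          (0.6 + 0.4 * sin(pi * k / dur))
      }
      idx <- onset + k - 1L
      idx_ok <- idx <= n
      for (ch in setdiff(layout, eog)) {
        w <- if (ch %in% central) 1 else 0.35
        samples[ch, idx[idx_ok]] <- samples[ch, idx[idx_ok]] +
          w * wave[idx_ok]
      }
      markers[[length(markers) + 1L]] <-
        data.frame(sample_index = onset, marker_type = type)
    }
    # anti-phase slow half-waves on the EOG pair during B1 runs
    r <- rle(stages == "B1")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- (starts[j] - 1L) * fs + 1L
      i1 <- ends[j] * fs
      tt <- seq_len(i1 - i0 + 1L) / fs
      f_sem <- runif(1, params$sem_freq_range[1], params$sem_freq_range[2])
      amp <- runif(1, params$sem_amp_range[1], params$sem_amp_range[2])
      wave <- amp * sin(2 * pi * f_sem * tt)
      samples[eog[1], i0:i1] <- samples[eog[1], i0:i1] + wave
      samples[eog[2], i0:i1] <- samples[eog[2], i0:i1] - wave
    }
    mk <- if (length(markers)) do.call(rbind, markers) else NULL
    structure(list(recording = recording(samples, fs = fs,
                                         channel_labels = layout,
                                         eog_pair = eog),
                   markers = normalize_markers(mk),
                   course = course),
              class = "vig_simulation")
  })
}

#' @export
print.vig_simulation <- function(x, ...) {
  cat(sprintf("<vig_simulation> %.1f min at %g Hz, %d marker(s)\n",
              x$recording$duration_s / 60, x$recording$fs,
              nrow(x$markers)))
  invisible(x)
}

#' Synthesize an eyes-closed calibration segment
#'
#' A short all-A1 segment with the same signal recipe, mimicking the
#' closed-eyes phase of the alpha-assessment maneuver that anchors the
#' subject's alpha scale.
#'
#' @param duration_s segment length (default 30 s).
#' @inheritParams simulate_recording
#' @return A [recording()].
#' @export
simulate_calibration_segment <- function(duration_s = 30,
                                         layout = default_layout(),
                                         fs = 200, seed = 1,
                                         params = signal_params()) {
  course <- stage_sequence(rep("A1", duration_s))
  simulate_recording(course, layout = layout, fs = fs, seed = seed,
                     params = params)$recording
}
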