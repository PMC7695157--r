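# Epoch features and the seven-stage vigilance classifier.

#' Classifier configuration
#'
#' Bundles the decision thresholds of the stage classifier. The
#' frontalization cut-points `r1 < r2` partition the anterior/posterior
#' alpha-power ratio into A1 (`r < r1`), A2 (`r1 <= r < r2`) and A3
#' (`r >= r2`); the absolute alpha and slow-wave thresholds come from the
#' subject's [calibrate()] profile. SEM parameters control the
#' slow-eye-movement detector feeding stage B1.
#'
#' @param calib optional [calibrate()] profile supplying the thresholds.
#' @param alpha_threshold,slowwave_threshold absolute thresholds in
#'   microvolt^2 (required if `calib` is `NULL`).
#' @param r1,r2 frontalization cut-points, `0 < r1 < r2`.
#' @param alpha_band,slow_band analysis bands in Hz.
#' @param sem_min_amp minimal SEM peak-to-peak amplitude in microvolts.
#' @param sem_max_corr maximal (i.e. most positive admissible) left/right
#'   EOG correlation; SEMs are anti-phase, default -0.5.
#' @param sem_band detection band in Hz for the EOG pair.
#' @param sem_window_s analysis window centred on each epoch (s).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(calib = NULL, alpha_threshold = NULL,
                              slowwave_threshold = NULL,
                              r1 = 0.5, r2 = 1.0,
                              alpha_band = c(8, 12), slow_band = c(2, 7),
                              sem_min_amp = 40, sem_max_corr = -0.5,
                              sem_band = c(0.05, 1), sem_window_s = 4) {
  if (!is.null(calib)) {
    stopifnot(inherits(calib, "calibration_profile"))
    if (calib$low_voltage_flag) {
      fail("calibration profile is low-voltage; alpha-based staging not applicable")
    }
    if (is.null(alpha_threshold)) alpha_threshold <- calib$alpha_threshold
    if (is.null(slowwave_threshold)) slowwave_threshold <- calib$slowwave_threshold
    alpha_band <- calib$alpha_band
  }
  if (is.null(alpha_threshold) || is.null(slowwave_threshold)) {
    fail("provide a calibration profile or explicit thresholds")
  }
  if (!(r1 > 0 && r1 < r2)) fail("frontalization cut-points need 0 < r1 < r2")
  structure(list(alpha_threshold = alpha_threshold,
                 slowwave_threshold = slowwave_threshold,
                 r1 = r1, r2 = r2,
                 alpha_band = alpha_band, slow_band = slow_band,
                 sem_min_amp = sem_min_amp, sem_max_corr = sem_max_corr,
                 sem_band = sem_band, sem_window_s = sem_window_s),
            class = "classifier_config")
}

#' Detect slow horizontal eye movements on the EOG pair
#'
#' Both EOG traces are band-passed to the sub-1 Hz range; an epoch is
#' SEM-positive when, within a window centred on it, (i) the smaller of the
#' two channels' peak-to-peak deflections reaches `sem_min_amp`, (ii) the
#' left/right traces are anti-phase (correlation at most `sem_max_corr`),
#' and (iii) the differential signal's energy below 0.5 Hz dominates its
#' energy in 0.5-2 Hz.
#'
#' @param eog_left,eog_right numeric EOG traces (microvolts), unfiltered.
#' @param fs sampling rate in Hz.
#' @param config a [classifier_config()] (only the `sem_*` fields are used).
#' @param n_epochs number of 1-s epochs to evaluate (default: all).
#' @return Logical vector, one flag per epoch.
#' @export
detect_sem <- function(eog_left, eog_right, fs,
                       config = classifier_config(alpha_threshold = 1,
                                                  slowwave_threshold = 1),
                       n_epochs = NULL) {
  fs <- as.integer(fs)
  if (length(eog_left) != length(eog_right)) {
    fail("EOG traces must have equal length")
  }
  if (is.null(n_epochs)) n_epochs <- length(eog_left) %/% fs
  nyq <- fs / 2
  bf <- signal::butter(2, config$sem_band / nyq, "pass")
  l <- signal::filtfilt(bf, eog_left)
  r <- signal::filtfilt(bf, eog_right)
  pad <- round((config$sem_window_s - 1) / 2 * fs)
  out <- logical(n_epochs)
  for (e in seq_len(n_epochs)) {
    i0 <- max(1L, (e - 1L) * fs + 1L - pad)
    i1 <- min(length(l), e * fs + pad)
    xl <- l[i0:i1]; xr <- r[i0:i1]
    amp <- min(diff(range(xl)), diff(range(xr)))
    if (amp < config$sem_min_amp) next
    cc <- suppressWarnings(cor(xl, xr))
    if (is.na(cc) || cc > config$sem_max_corr) next
    d <- (xl - xr) / 2
    nd <- length(d)
    sp <- Mod(fft(d))^2
    fr <- (seq_len(nd) - 1) * fs / nd
    slow <- sum(sp[fr > 0 & fr < 0.5])
    fast <- sum(sp[fr >= 0.5 & fr <= 2])
    out[e] <- slow > fast
  }
  out
}

#' Per-epoch spectral and ocular features
#'
#' For every 1-s epoch: mean alpha-band power over the anterior and
#' posterior ROIs, mean slow-wave (2-7 Hz) power over the global ROI
#' (Hann-windowed periodogram, ROI mean over channels), the SEM flag from
#' [detect_sem()] and the spindle/K-complex marker overlapping the epoch.
#'
#' @param rec a [recording()] (EEG channels filtered; EOG raw).
#' @param grid the [segment_epochs()] grid (artifact flags are copied).
#' @param rois ROI map as from [default_rois()]; must cover anterior and
#'   posterior regions.
#' @param config a [classifier_config()] (bands and SEM parameters).
#' @param markers optional marker data.frame (see [read_markers()]) or path.
#' @return A data.frame with one row per epoch: `epoch`, `alpha_anterior`,
#'   `alpha_posterior`, `slowwave`, `sem`, `marker` (`"none"`, `"spindle"`,
#'   `"kcomplex"`), `artifact`.
#' @export
extract_features <- function(rec, grid, rois = default_rois(rec$channel_labels),
                             config = classifier_config(alpha_threshold = 1,
                                                        slowwave_threshold = 1),
                             markers = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(grid, "epoch_grid"))
  if (rec$fs < 100) fail("feature extraction needs fs >= 100 Hz")
  n <- grid$n_epochs
  for (nm in c("anterior", "posterior", "global")) {
    if (length(rois[[nm]]) == 0L) fail("ROI '%s' contains no channels", nm)
  }
  alpha_ant <- roi_band_powers(rec, n, rois$anterior, config$alpha_band)
  alpha_post <- roi_band_powers(rec, n, rois$posterior, config$alpha_band)
  slow <- roi_band_powers(rec, n, rois$global, config$slow_band)
  sem <- detect_sem(rec$samples[rec$eog_pair[1], ],
                    rec$samples[rec$eog_pair[2], ],
                    rec$fs, config, n_epochs = n)
  marker <- rep("none", n)
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- read_markers(markers)
    markers <- normalize_markers(markers)
    ep <- ceiling(markers$sample_index / rec$fs)
    keep <- ep >= 1 & ep <= n
    marker[ep[keep]] <- markers$marker_type[keep]
  }
  data.frame(epoch = seq_len(n),
             alpha_anterior = alpha_ant, alpha_posterior = alpha_post,
             slowwave = slow, sem = sem, marker = marker,
             artifact = grid$artifact)
}

# vectorised decision ladder over a feature table; NA for artifact epochs
classify_features <- function(features, config) {
  n <- nrow(features)
  out <- rep(NA_character_, n)
  live <- !features$artifact
  alpha_max <- pmax(features$alpha_anterior, features$alpha_posterior)
  ratio <- features$alpha_anterior / features$alpha_posterior
  is_c <- live & features$marker != "none"
  is_b23 <- live & !is_c &
    features$slowwave >= config$slowwave_threshold &
    alpha_max < config$alpha_threshold
  is_a <- live & !is_c & !is_b23 & alpha_max >= config$alpha_threshold
  out[is_c] <- "C"
  out[is_b23] <- "B2/3"
  out[is_a & ratio < config$r1] <- "A1"
  out[is_a & ratio >= config$r1 & ratio < config$r2] <- "A2"
  out[is_a & ratio >= config$r2] <- "A3"
  rest <- live & is.na(out)
  out[rest & features$sem] <- "B1"
  out[rest & !features$sem] <- "0"
  out
}

#' Classify a single epoch
#'
#' Decision ladder: (1) a spindle/K-complex marker forces stage C;
#' (2) slow-wave power at or above the slow-wave threshold with alpha below
#' the alpha threshold gives B2/3; (3) alpha power (max of anterior and
#' posterior ROI) at or above the alpha threshold enters the A branch,
#' subdivided by the anterior/posterior ratio via `r1`/`r2`; (4) otherwise a
#' SEM flag gives B1; (5) otherwise stage 0.
#'
#' @param features one row of [extract_features()] output (or a list with
#'   the same fields); must not be artifact-flagged.
#' @param config a [classifier_config()].
#' @return A single stage label.
#' @export
classify_epoch <- function(features, config) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == 1L)
  if (isTRUE(features$artifact)) {
    fail("cannot classify an artifact epoch; mask it instead")
  }
  classify_features(features, config)
}

#' Classify a whole recording into a stage sequence
#'
#' Runs the full per-subject chain: EEG filtering, 1-s segmentation,
#' amplitude artifact screening, feature extraction and the stage decision
#' ladder. Deterministic given its inputs.
#'
#' @param rec a raw [recording()].
#' @param calib the subject's [calibrate()] profile.
#' @param config optional [classifier_config()]; derived from `calib` by
#'   default.
#' @param markers optional spindle/K-complex markers (data.frame or path).
#' @param rois ROI map.
#' @param amp_limit artifact peak-to-peak limit in microvolts.
#' @param filter apply [filter_recording()] first (default `TRUE`).
#' @return A [stage_sequence()]; artifact epochs carry no stage.
#' @export
classify_recording <- function(rec, calib, config = NULL, markers = NULL,
                               rois = default_rois(rec$channel_labels),
                               amp_limit = 200, filter = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(config)) config <- classifier_config(calib)
  if (filter) rec <- filter_recording(rec)
  grid <- segment_epochs(rec)
  grid <- screen_artifacts(rec, grid, amp_limit = amp_limit)
  feats <- extract_features(rec, grid, rois = rois, config = config,
                            markers = markers)
  stage_sequence(classify_features(feats, config), artifact = grid$artifact)
}

#' Automatic spindle / K-complex detection (non-canonical)
#'
#' A simple amplitude-duration template detector intended only for
#' synthetic recordings: stage C is canonically bound to *manually set*
#' markers, and this detector is no substitute for expert marking on real
#' data. Spindles: the 12-15 Hz envelope of the central ROI mean exceeds
#' `spindle_factor` times its own median for 0.4-1.2 s. K-complexes: the
#' 0.5-2 Hz fronto-central mean crosses below `-k_threshold` microvolts.
#'
#' @param rec a [recording()].
#' @param spindle_band,spindle_factor,spindle_dur_s spindle template
#'   parameters.
#' @param k_band,k_threshold K-complex template parameters.
#' @param refractory_s minimal separation between detected events.
#' @return A marker data.frame (`sample_index`, `marker_type`).
#' @export
detect_events <- function(rec, spindle_band = c(12, 15), spindle_factor = 4,
                          spindle_dur_s = c(0.4, 1.2),
                          k_band = c(0.5, 2), k_threshold = 25,
                          refractory_s = 1) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  nyq <- fs / 2
  central <- intersect(c("C3", "Cz", "C4", "F3", "Fz", "F4"),
                       rec$channel_labels)
  if (length(central) == 0L) central <- eeg_channels(rec)
  m <- colMeans(rec$samples[central, , drop = FALSE])
  runs_above <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  out <- list()
  # spindles: rectified band envelope above an adaptive threshold
  sp <- signal::filtfilt(signal::butter(2, spindle_band / nyq, "pass"), m)
  env <- signal::filtfilt(signal::butter(2, 4 / nyq, "low"), abs(sp))
  thr <- spindle_factor * median(env)
  seg <- runs_above(env > thr)
  if (nrow(seg) > 0) {
    dur <- (seg[, 2] - seg[, 1] + 1) / fs
    keep <- dur >= spindle_dur_s[1] & dur <= spindle_dur_s[2]
    if (any(keep)) {
      out$sp <- data.frame(sample_index = seg[keep, 1],
                           marker_type = "spindle")
    }
  }
  # K-complexes: deep negative slow-wave excursion
  kw <- signal::filtfilt(signal::butter(2, k_band / nyq, "pass"), m)
  seg <- runs_above(kw < -k_threshold)
  if (nrow(seg) > 0) {
    out$k <- data.frame(sample_index = seg[, 1], marker_type = "kcomplex")
  }
  if (length(out) == 0L) return(normalize_markers(NULL))
  mk <- do.call(rbind, out)
  mk <- mk[order(mk$sample_index), , drop = FALSE]
  # enforce the refractory period across event types
  keep <- c(TRUE, diff(mk$sample_index) > refractory_s * fs)
  normalize_markers(mk[keep, , drop = FALSE])
}
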