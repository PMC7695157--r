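# Recording container, 10-20 layout, ROI groupings, filtering, 1-s
# segmentation, artifact screening and eyes-closed calibration.

#' Default 10-20 channel layout with a horizontal EOG pair
#'
#' @return Character vector of 19 scalp labels plus `EOGL`/`EOGR`.
#' @export
default_layout <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2",
    "EOGL", "EOGR")
}

#' Default region-of-interest channel groups
#'
#' Scalp-ROI mean band powers stand in for source-space powers: the
#' anterior ROI carries the frontalization evidence, the occipito-parietal
#' ROI the resting alpha reference, and the global ROI the slow-wave
#' evidence.
#'
#' @param labels channel labels to intersect with (default: full layout).
#' @return Named list of character vectors: `anterior`, `posterior`,
#'   `global`.
#' @export
default_rois <- function(labels = default_layout()) {
  eeg <- setdiff(labels, grep("EOG", labels, value = TRUE))
  list(anterior = intersect(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"), eeg),
       posterior = intersect(c("P3", "Pz", "P4", "O1", "O2"), eeg),
       global = eeg)
}

#' Construct a multichannel recording
#'
#' @param samples numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels one label per row of `samples`.
#' @param eog_pair the two horizontal EOG labels (must be present).
#' @return An object of class `recording`: `samples` (with labelled rows),
#'   `fs`, `channel_labels`, `eog_pair`, `duration_s`.
#' @export
recording <- function(samples, fs, channel_labels,
                      eog_pair = c("EOGL", "EOGR")) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    fail("sampling rate must be a positive number")
  }
  if (nrow(samples) != length(channel_labels)) {
    fail("need one channel label per sample row (%d rows, %d labels)",
         nrow(samples), length(channel_labels))
  }
  missing_eog <- setdiff(eog_pair, channel_labels)
  if (length(eog_pair) != 2L || length(missing_eog) > 0L) {
    fail("recording lacks the EOG pair channel(s): %s",
         paste(if (length(missing_eog)) missing_eog else eog_pair,
               collapse = ", "))
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels, eog_pair = eog_pair,
                 duration_s = ncol(samples) / fs),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %.1f s at %g Hz (EOG: %s)\n",
              nrow(x$samples), x$duration_s, x$fs,
              paste(x$eog_pair, collapse = "/")))
  invisible(x)
}

eeg_channels <- function(rec) setdiff(rec$channel_labels, rec$eog_pair)

#' Band-pass, low-pass and notch filtering of a recording
#'
#' Applies zero-phase (forward-backward) Butterworth filters to all EEG
#' channels: high pass 0.5 Hz (order 2), low pass 70 Hz (order 4) and a
#' notch implemented as a 4-Hz-wide band stop around 50 Hz (order 2). The
#' EOG pair is passed through unfiltered because the slow-eye-movement
#' detector needs the sub-0.5 Hz band the high pass would remove.
#'
#' @param rec a [recording()].
#' @param hp,lp,notch cut-off / notch frequencies in Hz; `NULL` disables the
#'   respective filter.
#' @return The filtered [recording()].
#' @export
filter_recording <- function(rec, hp = 0.5, lp = 70, notch = 50) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!is.null(lp) && lp >= nyq) {
    fail("low-pass cut-off (%g Hz) must lie below the Nyquist frequency (%g Hz)",
         lp, nyq)
  }
  filts <- list()
  if (!is.null(hp)) filts <- c(filts, list(signal::butter(2, hp / nyq, "high")))
  if (!is.null(lp)) filts <- c(filts, list(signal::butter(4, lp / nyq, "low")))
  if (!is.null(notch)) {
    filts <- c(filts, list(signal::butter(2, c(notch - 2, notch + 2) / nyq,
                                          "stop")))
  }
  out <- rec
  for (ch in eeg_channels(rec)) {
    x <- rec$samples[ch, ]
    for (f in filts) x <- signal::filtfilt(f, x)
    out$samples[ch, ] <- x
  }
  out
}

#' Cut a recording into contiguous 1-s epochs
#'
#' Non-overlapping, contiguous epochs of exactly one second; a trailing
#' partial second is dropped.
#'
#' @param rec a [recording()] of at least 1 s.
#' @return An object of class `epoch_grid`: `epoch_length_s` (1),
#'   `n_epochs`, `fs` and an all-false `artifact` mask.
#' @export
segment_epochs <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  n_epochs <- floor(rec$duration_s)
  if (n_epochs < 1) {
    fail("recording spans %.2f s; at least one full second is required",
         rec$duration_s)
  }
  structure(list(epoch_length_s = 1L, n_epochs = as.integer(n_epochs),
                 fs = rec$fs, artifact = rep(FALSE, n_epochs)),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d x %d s epochs, %d artifact-flagged\n",
              x$n_epochs, x$epoch_length_s, sum(x$artifact)))
  invisible(x)
}

#' Flag epochs containing high-amplitude artifacts
#'
#' An epoch is flagged when the peak-to-peak amplitude of any EEG channel
#' within it exceeds `amp_limit`. Flags are sticky: epochs already flagged
#' stay flagged.
#'
#' @param rec a [recording()] (filter first for meaningful amplitudes).
#' @param grid the [segment_epochs()] grid of `rec`.
#' @param amp_limit peak-to-peak limit in microvolts (default 200).
#' @return The updated `epoch_grid`.
#' @export
screen_artifacts <- function(rec, grid, amp_limit = 200) {
  stopifnot(inherits(rec, "recording"), inherits(grid, "epoch_grid"))
  if (!is.numeric(amp_limit) || amp_limit <= 0) {
    fail("amp_limit must be positive")
  }
  fs <- as.integer(rec$fs)
  n <- grid$n_epochs
  flagged <- rep(FALSE, n)
  for (ch in eeg_channels(rec)) {
    x <- matrix(rec$samples[ch, seq_len(n * fs)], nrow = fs)
    p2p <- apply(x, 2, max) - apply(x, 2, min)
    flagged <- flagged | p2p > amp_limit
  }
  grid$artifact <- grid$artifact | flagged
  grid
}

# ---- band power -----------------------------------------------------------

# per-epoch band power (uV^2) of one channel: Hann-windowed periodogram on
# each 1-s epoch, one-sided, summed over bins inside [band[1], band[2]] Hz.
channel_band_powers <- function(x, fs, n_epochs, band) {
  fs <- as.integer(fs)
  m <- matrix(x[seq_len(n_epochs * fs)], nrow = fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(fs) / (fs + 1)) # Hann
  m <- m * w
  sp <- stats::mvfft(m)
  # PSD normalised so that the one-sided sum approximates the epoch variance
  scale <- 1 / (fs * mean(w^2))
  nfreq <- fs %/% 2 + 1
  p <- Mod(sp[seq_len(nfreq), , drop = FALSE])^2 * scale / fs
  p[2:(nfreq - 1), ] <- 2 * p[2:(nfreq - 1), ]
  freqs <- seq(0, fs / 2, by = 1)
  sel <- freqs >= band[1] & freqs <= band[2]
  colSums(p[sel, , drop = FALSE]) # per-bin width is 1 Hz; sums to the variance
}

# mean band power over an ROI (channels averaged after per-channel powers)
roi_band_powers <- function(rec, n_epochs, channels, band) {
  if (length(channels) == 0L) fail("ROI contains no channels")
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing) > 0L) {
    fail("ROI channel(s) absent from recording: %s",
         paste(missing, collapse = ", "))
  }
  acc <- 0
  for (ch in channels) {
    acc <- acc + channel_band_powers(rec$samples[ch, ], rec$fs, n_epochs, band)
  }
  acc / length(channels)
}

# ---- calibration ----------------------------------------------------------

#' Derive subject-specific classifier thresholds from an eyes-closed segment
#'
#' The calibration segment (eyes-closed rest with intact posterior alpha,
#' e.g. the closed-eyes phase of an alpha-assessment maneuver) anchors the
#' subject's alpha scale: `alpha_threshold = f_alpha *` median posterior
#' alpha power per epoch, `slowwave_threshold = f_slow *` the same
#' reference. Subjects whose median posterior alpha power falls below
#' `low_voltage_floor` are flagged as low-voltage EEG, for which the
#' alpha-based staging is not applicable.
#'
#' @param rec a [recording()] of at least `min_duration_s` seconds.
#' @param f_alpha fraction of the alpha reference used as alpha threshold
#'   (default 0.25).
#' @param f_slow fraction used as slow-wave threshold (default 1).
#' @param low_voltage_floor absolute floor in microvolt^2 (default 10).
#' @param alpha_band alpha band in Hz (default 8-12).
#' @param rois ROI map; only `posterior` is used.
#' @param min_duration_s minimal calibration length (default 10 s).
#' @return An object of class `calibration_profile`:
#'   `eyes_closed_alpha_power`, `alpha_threshold`, `slowwave_threshold`,
#'   `low_voltage_flag`, `iaf_hz` (posterior spectral peak in 7-13 Hz) and
#'   the configuration used.
#' @export
calibrate <- function(rec, f_alpha = 0.25, f_slow = 1.0,
                      low_voltage_floor = 10, alpha_band = c(8, 12),
                      rois = default_rois(rec$channel_labels),
                      min_duration_s = 10) {
  stopifnot(inherits(rec, "recording"))
  if (rec$duration_s < min_duration_s) {
    fail("calibration segment spans %.1f s; at least %g s are required",
         rec$duration_s, min_duration_s)
  }
  n_epochs <- floor(rec$duration_s)
  ref <- median(roi_band_powers(rec, n_epochs, rois$posterior, alpha_band))
  low_voltage <- ref < low_voltage_floor
  # individual alpha frequency: posterior spectral peak in the extended band
  peak <- vapply(7:13, function(f) {
    mean(roi_band_powers(rec, n_epochs, rois$posterior, c(f - 0.5, f + 0.5)))
  }, numeric(1))
  structure(list(eyes_closed_alpha_power = ref,
                 alpha_threshold = f_alpha * ref,
                 slowwave_threshold = f_slow * ref,
                 low_voltage_flag = low_voltage,
                 iaf_hz = (7:13)[which.max(peak)],
                 f_alpha = f_alpha, f_slow = f_slow,
                 low_voltage_floor = low_voltage_floor,
                 alpha_band = alpha_band),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(paste0("<calibration_profile> alpha ref %.1f uV^2, ",
                     "thresholds alpha %.1f / slow %.1f uV^2%s, IAF %d Hz\n"),
              x$eyes_closed_alpha_power, x$alpha_threshold,
              x$slowwave_threshold,
              if (x$low_voltage_flag) " [LOW VOLTAGE]" else "", x$iaf_hz))
  invisible(x)
}
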