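# Minimal European Data Format (EDF) reader and writer.
#
# Implements the classic 16-bit EDF layout with one-second data records,
# which is sufficient for the recordings this package produces and
# consumes. (No EDF+ annotations; event markers travel in a separate
# plain-text file, see read_markers().)

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' One-second data records, 16-bit samples, symmetric physical scaling per
#' channel. A trailing partial second is dropped (EDF records must be
#' complete). Header date/time fields are fixed placeholders so that
#' repeated writes of the same data are byte-identical.
#'
#' @param rec a [recording()] with integer sampling rate.
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields (max 80 chars).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X",
                      recording_id = "synthetic resting EEG") {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (fs != round(fs)) fail("EDF export needs an integer sampling rate")
  fs <- as.integer(fs)
  n_rec <- floor(rec$duration_s)
  if (n_rec < 1) fail("recording shorter than one EDF record (1 s)")
  ns <- nrow(rec$samples)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  phys_max <- pmax(apply(abs(x), 1, max) * 1.01, 1)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(patient_id, 80)
  wr(recording_id, 80)
  wr("01.01.20", 8)  # fixed placeholders: deterministic output
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                      # transducer
  for (i in seq_len(ns)) wr("uV", 8)                     # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.6g", -phys_max[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr(-dig_max, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)                      # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round(sweep(x, 1, phys_max / dig_max, "/"))
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(ns)) {
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the classic EDF layout written by [write_edf()] (equal sampling
#' rate across signals). Channel labels are trimmed; the horizontal EOG
#' pair is identified by labels containing `"EOG"`.
#'
#' @param path EDF file path.
#' @param eog_pair optional explicit EOG labels; by default the first two
#'   labels containing `"EOG"`.
#' @return A [recording()] in microvolts.
#' @export
read_edf <- function(path, eog_pair = NULL) {
  if (!file.exists(path)) fail("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") fail("unreadable EDF header in %s (version '%s')",
                           path, version)
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(ns) || ns < 1) {
    fail("unreadable EDF header in %s", path)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    fail("mixed sampling rates per signal are not supported")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <-
        phys_min[i] + (d - dig_min[i]) * gain
    }
  }
  if (is.null(eog_pair)) {
    eog <- grep("EOG", labels, value = TRUE)
    if (length(eog) < 2L) {
      fail("EDF file %s lacks a horizontal EOG pair (labels containing 'EOG')",
           path)
    }
    eog_pair <- eog[1:2]
  }
  recording(out, fs = fs, channel_labels = labels, eog_pair = eog_pair)
}

#' Read and write spindle / K-complex marker files
#'
#' Markers travel as a two-column tab-separated text file with header
#' `sample_index` (1-based sample of event onset) and `marker_type`
#' (`SPINDLE` or `KCOMPLEX`).
#'
#' @param markers data.frame with columns `sample_index` and `marker_type`.
#' @param path file path.
#' @return `read_markers()` returns the normalized marker data.frame;
#'   `write_markers()` returns `path` invisibly.
#' @export
write_markers <- function(markers, path) {
  markers <- normalize_markers(markers)
  out <- data.frame(sample_index = markers$sample_index,
                    marker_type = toupper(markers$marker_type))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) fail("marker file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character"))
  normalize_markers(df)
}

normalize_markers <- function(markers) {
  if (is.null(markers) || nrow(as.data.frame(markers)) == 0L) {
    return(data.frame(sample_index = numeric(0),
                      marker_type = character(0)))
  }
  markers <- as.data.frame(markers)
  if (!all(c("sample_index", "marker_type") %in% names(markers))) {
    fail("markers need columns 'sample_index' and 'marker_type'")
  }
  type <- tolower(trimws(markers$marker_type))
  type[type %in% c("k", "kc", "k-complex", "kcomplex")] <- "kcomplex"
  type[type %in% c("sp", "spindle")] <- "spindle"
  bad <- !type %in% c("spindle", "kcomplex")
  if (any(bad)) {
    fail("unknown marker type(s): %s",
         paste(unique(markers$marker_type[bad]), collapse = ", "))
  }
  data.frame(sample_index = as.numeric(markers$sample_index),
             marker_type = type)
}
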