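# The seven-stage vigilance ladder and the per-second stage sequence.

# canonical labels, ordered by numeric score 1..7
.STAGE_LABELS <- c("C", "B2/3", "B1", "A3", "A2", "A1", "0")

#' The seven vigilance stages and their numeric scores
#'
#' The ladder runs from sleep onset to activated wakefulness:
#' C (sleep onset; spindles / K-complexes) = 1, B2/3 (theta/delta-dominated
#' drowsiness) = 2, B1 (low-voltage drowsiness with slow eye movements) = 3,
#' A3 = 4, A2 = 5 (frontalized alpha), A1 (occipital alpha) = 6 and
#' 0 (activated wakefulness) = 7. The mapping is fixed and bijective.
#'
#' @return A data.frame with columns `label` and `score`.
#' @export
#' @examples
#' vigilance_stages()
vigilance_stages <- function() {
  data.frame(label = .STAGE_LABELS, score = 1:7, stringsAsFactors = FALSE)
}

# accept common spelling variants for stage labels
normalize_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("B23", "B2-3", "B2/3")] <- "B2/3"
  x[x %in% c("O", "ZERO")] <- "0"
  x
}

#' Convert stage labels to numeric vigilance scores and back
#'
#' @param stage character vector of stage labels (`"0"`, `"A1"`, `"A2"`,
#'   `"A3"`, `"B1"`, `"B2/3"` (alias `"B23"`), `"C"`).
#' @param score integer vector of scores in 1..7.
#' @return `stage_score()` returns integer scores; `score_stage()` returns
#'   stage labels.
#' @export
#' @examples
#' stage_score(c("C", "A1", "0"))
#' score_stage(1:7)
stage_score <- function(stage) {
  stage <- normalize_stage(stage)
  out <- match(stage, .STAGE_LABELS)
  bad <- !is.na(stage) & is.na(out)
  if (any(bad)) {
    fail("unknown vigilance stage label(s): %s",
         paste(unique(stage[bad]), collapse = ", "))
  }
  out
}

#' @rdname stage_score
#' @export
score_stage <- function(score) {
  if (any(!is.na(score) & (score < 1 | score > 7 | score != round(score)))) {
    fail("vigilance scores must be integers in 1..7")
  }
  .STAGE_LABELS[as.integer(score)]
}

#' Construct a per-second vigilance stage sequence
#'
#' The stage sequence is the central intermediate of the pipeline: one stage
#' label per second plus an artifact mask. Artifact seconds carry no stage
#' label (they are stored as `NA` and excluded from every metric).
#'
#' @param stages character vector of per-second stage labels; entries at
#'   artifact positions may be anything (they are replaced by `NA`).
#' @param artifact logical artifact mask, same length as `stages`
#'   (default: all `FALSE`).
#' @return An object of class `stage_sequence` with elements `stages`,
#'   `artifact` and `epoch_length_s` (fixed at 1).
#' @export
#' @examples
#' s <- stage_sequence(rep(c("A1", "0"), 30))
#' length(s)
stage_sequence <- function(stages, artifact = NULL) {
  stages <- normalize_stage(stages)
  n <- length(stages)
  if (n < 1L) fail("a stage sequence must contain at least one second")
  if (is.null(artifact)) artifact <- rep(FALSE, n)
  artifact <- as.logical(artifact)
  if (length(artifact) != n) {
    fail("artifact mask length (%d) must equal sequence length (%d)",
         length(artifact), n)
  }
  if (anyNA(artifact)) fail("artifact mask must not contain NA")
  stages[artifact] <- NA_character_
  ok <- is.na(stages) | stages %in% .STAGE_LABELS
  if (!all(ok)) {
    fail("unknown vigilance stage label(s): %s",
         paste(unique(stages[!ok]), collapse = ", "))
  }
  if (any(is.na(stages) & !artifact)) {
    fail("non-artifact seconds must carry a stage label")
  }
  structure(list(stages = stages, artifact = artifact, epoch_length_s = 1L),
            class = "stage_sequence")
}

#' @export
length.stage_sequence <- function(x) length(x$stages)

#' @export
print.stage_sequence <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<stage_sequence> %d s (%.1f min), %d artifact second(s)\n",
              n, n / 60, sum(x$artifact)))
  tab <- table(factor(x$stages, levels = .STAGE_LABELS))
  print(tab)
  invisible(x)
}

#' Numeric score course of a stage sequence
#'
#' @param seq a [stage_sequence()].
#' @return Integer vector of per-second scores (`NA` at artifact seconds).
#' @export
stage_scores <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  stage_score(seq$stages)
}

#' Read and write per-second stage sequences as tab-separated text
#'
#' The on-disk format has columns `second`, `stage` and `artifact`
#' (0/1); artifact seconds carry `stage = "NA"`.
#'
#' @param seq a [stage_sequence()].
#' @param path file path.
#' @return `read_stage_sequence()` returns a [stage_sequence()];
#'   `write_stage_sequence()` returns `path` invisibly.
#' @export
write_stage_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "stage_sequence"))
  df <- data.frame(second = seq_along(seq$stages),
                   stage = ifelse(seq$artifact, "NA", seq$stages),
                   artifact = as.integer(seq$artifact))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_sequence
#' @export
read_stage_sequence <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer"))
  stage_sequence(df$stage, artifact = df$artifact == 1L)
}
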