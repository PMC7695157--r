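# Prototype arousal-regulation time courses and least-squares assignment.

#' Prototypical per-minute MVV time courses
#'
#' The regulation model compares each subject's per-minute mean vigilance
#' course with fixed prototype curves and assigns the closest one. The
#' published model is verbal; the numeric default curves used here are:
#' hyperstable, constant at the A1 level (6); stable, constant at the A2
#' level (5); adaptive, linear decline from 6 to 2 over the recording;
#' unstable, decline from 6 to 2 within the first quartile, then constant 2.
#' The three-prototype model merges stable and hyperstable into one constant
#' curve at level 6.
#'
#' @param model `"three"` or `"four"`.
#' @param duration_min course length in minutes (>= 4).
#' @param levels named numeric list overriding curve anchor levels:
#'   `top` (default 6), `floor` (2), `stable` (5), `hyperstable` (6).
#' @return A named list of numeric curves (class `prototype_set`); names are
#'   regulation labels (`"stable"` denotes the merged curve in the
#'   three-prototype model).
#' @export
#' @examples
#' lengths(build_prototypes("four", 20))
build_prototypes <- function(model = c("three", "four"), duration_min = 20,
                             levels = list()) {
  model <- match.arg(model)
  if (!is.numeric(duration_min) || duration_min < 4) {
    fail("prototype curves need a duration of at least 4 minutes")
  }
  m <- as.integer(duration_min)
  lv <- utils::modifyList(list(top = 6, floor = 2, stable = 5,
                               hyperstable = 6), levels)
  k <- max(2L, as.integer(round(m / 4)))
  adaptive <- seq(lv$top, lv$floor, length.out = m)
  unstable <- c(seq(lv$top, lv$floor, length.out = k), rep(lv$floor, m - k))
  curves <- if (model == "four") {
    list(hyperstable = rep(lv$hyperstable, m),
         stable = rep(lv$stable, m),
         adaptive = adaptive,
         unstable = unstable)
  } else {
    list(stable = rep(lv$hyperstable, m),
         adaptive = adaptive,
         unstable = unstable)
  }
  if (any(unlist(curves) < 1 | unlist(curves) > 7)) {
    fail("prototype curve values must lie in [1, 7]")
  }
  structure(curves, class = "prototype_set", model = model)
}

#' Assign an MVV course to its closest prototype
#'
#' Computes the sum of squared deviations between the per-minute MVV course
#' and every prototype curve and assigns the label with the smallest sum.
#' Missing minutes are excluded pairwise. Ties are broken toward the more
#' stable prototype (hyperstable > stable > adaptive > unstable), which is
#' listed first in [build_prototypes()] output.
#'
#' @param mvv an `mvv_course` from [mean_vigilance_value()] or a numeric
#'   per-minute vector.
#' @param prototypes a `prototype_set` from [build_prototypes()].
#' @return A list of class `prototype_assignment`: `model`, `label`, `ssq`
#'   (of the assigned curve) and `ssq_all` (named vector).
#' @export
#' @examples
#' pr <- build_prototypes("four", 20)
#' assign_prototype(rep(6, 20), pr)$label
assign_prototype <- function(mvv, prototypes) {
  stopifnot(inherits(prototypes, "prototype_set"))
  course <- if (inherits(mvv, "mvv_course")) mvv$per_minute else as.numeric(mvv)
  m <- length(prototypes[[1L]])
  if (length(course) != m) {
    fail("course length (%d) must equal prototype length (%d)",
         length(course), m)
  }
  keep <- !is.na(course)
  if (!any(keep)) fail("all minutes of the course are missing")
  ssq <- vapply(prototypes, function(p) sum((course[keep] - p[keep])^2),
                numeric(1))
  best <- which(ssq == min(ssq))[1L]  # order encodes the stability tie-break
  structure(list(model = attr(prototypes, "model"),
                 label = names(prototypes)[best],
                 ssq = unname(ssq[best]), ssq_all = ssq),
            class = "prototype_assignment")
}

#' @export
print.prototype_assignment <- function(x, ...) {
  cat(sprintf("<prototype_assignment> %s-prototype model: %s (ssq = %.2f)\n",
              x$model, x$label, x$ssq))
  invisible(x)
}

#' Group-by-prototype contingency table
#'
#' @param labels character vector of assigned prototype labels.
#' @param group factor or character vector of group membership, same length.
#' @param prototype_levels optional label ordering for the columns.
#' @return A contingency table (groups x prototypes) whose rows sum to the
#'   group sizes.
#' @export
prototype_distribution <- function(labels, group, prototype_levels = NULL) {
  if (length(labels) != length(group)) {
    fail("labels and group must have the same length")
  }
  group <- as.factor(group)
  if (any(table(group) == 0L)) {
    fail("every group must contain at least one subject")
  }
  if (is.null(prototype_levels)) {
    prototype_levels <- intersect(c("hyperstable", "stable", "adaptive",
                                    "unstable"), unique(labels))
  }
  table(group = group,
        prototype = factor(labels, levels = prototype_levels))
}
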