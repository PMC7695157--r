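# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a sub-stream seed from a global seed
#'
#' All stochastic generators in the package are driven by one global seed;
#' per-subject and per-component streams are derived with a fixed
#' Lehmer-style mixing step so that whole cohorts are reproducible and
#' individual subjects can be re-simulated in isolation.
#'
#' @param seed integer global seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, 0:3)
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), all(is.finite(index)))
  m <- 2147483647 # 2^31 - 1; keeps every derived seed a valid R integer
  s <- as.double(seed) %% m
  x <- (s * 48271 + (as.double(index) + 1) * 16807 + 11) %% m
  as.integer(x)
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# stop() with sprintf-style formatting, no call in message
fail <- function(...) stop(sprintf(...), call. = FALSE)
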