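# Seed plumbing: every stochastic operation runs under a locally scoped
# seed so that (inputs, seed) -> outputs is a pure function and the
# caller's RNG stream is left untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage sub-seed from a master seed
#'
#' Stages of the pipeline (simulation, featurisation, training) draw their
#' randomness from sub-seeds computed deterministically from one master
#' seed, so individual stages can be re-run in isolation and still
#' reproduce the full-pipeline artifacts.
#'
#' @param master integer master seed.
#' @param stage stage name (any character scalar) or integer offset.
#' @param index optional sample index within the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage = 0L, index = 0L) {
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  # exact in double arithmetic: all intermediates stay below 2^53
  h <- (as.numeric(master) * 48271 + off * 16807 + as.numeric(index) * 69621)
  as.integer(h %% (2^31 - 3) + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
is_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
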