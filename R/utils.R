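# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a top-level seed
#'
#' All randomness in a run flows from one top-level seed; each module draws
#' from its own named substream so stages are independently reproducible.
#' The derivation is a small deterministic hash of the stream name folded
#' into the seed, kept below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stream character stream name, e.g. "carriers", "cohort", "lists".
#' @return integer seed for the substream.
#' @export
#' @examples
#' substream_seed(1, "carriers")
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 2147483 * 1000 + h) %% 2147483647)
}

rms <- function(x) sqrt(mean(x^2))

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_domain <- function(...) stop(..., call. = FALSE)
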