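# internal helpers shared across modules

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sigdiscord_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

abort_validation <- function(msg, ...) abort(msg, "sigdiscord_validation_error", ...)
abort_format     <- function(msg, ...) abort(msg, "sigdiscord_format_error", ...)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators behave as
#' pure functions of their arguments.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("seed must be a single integer, got %s", deparse(seed))
  }
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

# derive a per-stage 32-bit sub-seed from a run seed and a stage name, so
# stochastic stages are independent of execution order
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
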