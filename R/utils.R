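#' @keywords internal
#' @noRd
sct_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "scatterct_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Run an expression with a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores
#' the previous RNG state so no package function perturbs global
#' random-number state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sct_stop("invalid_argument", "seed must be a single integer")
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

#' Derive a per-stage seed from a master seed
#'
#' Deterministic mixing of a master seed, a stage label and an index so
#' each stochastic pipeline stage gets an independent, reproducible
#' stream. The result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"buckets"`.
#' @param index optional integer (e.g. angle index), default 0.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "buckets", 3)
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.double(master) * 2654435761 + h * 97003 + as.double(index) * 11939) %% (2^31 - 1)
  as.integer(floor(x))
}

# check a scalar is a positive finite number
#' @noRd
assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    sct_stop("invalid_argument", "%s must be a single positive number (got %s)",
             name, paste(format(x), collapse = ","))
  }
  invisible(x)
}

#' @noRd
is_pow2 <- function(n) {
  n == as.integer(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
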