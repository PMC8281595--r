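# Internal helpers shared across modules.

#' Signal a typed omicsurv error
#'
#' All recoverable failure modes carry a machine-readable condition class
#' (`omicsurv_<type>_error`) so callers (and the ensemble filter) can branch on
#' them rather than parse messages.
#'
#' @param msg character message.
#' @param type short identifier, e.g. "parse", "alignment", "no_survival_signal".
#' @param ... fields attached to the condition.
#' @noRd
abort_omicsurv <- function(msg, type = "generic", ...) {
  cond <- structure(
    class = c(paste0("omicsurv_", type, "_error"), "omicsurv_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's RNG stream; every stochastic operation takes an explicit seed.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rescale a numeric vector linearly onto [0, 1]; constant input -> error info
# left to callers.
rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_omicsurv(sprintf("`%s` must be a single finite number", name),
                   "argument")
}
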