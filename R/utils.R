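#' @keywords internal
"_PACKAGE"

# Structured errors: every user-facing failure carries a condition class so
# callers (and the pipeline driver) can distinguish configuration problems
# from contract violations without parsing messages.
rc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "riboclean_error")))
}

rc_warn <- function(msg, class = "riboclean_warning") {
  warning(warningCondition(msg, class = c(class, "riboclean_warning")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so that seeded package functions do not disturb the
#' caller's random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rc_stop("a single finite integer seed is required", "riboclean_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Derive a stage seed from a root seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97L * offset) %% (.Machine$integer.max - 1L))
}
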