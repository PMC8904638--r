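# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards; `seed = NULL` leaves the RNG stream untouched.  All
#' simulation functions in the package route their randomness through this
#' helper so that one master seed governs a whole analysis.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
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
  force(expr)
}

# Stage-local seeds are derived from one master seed by fixed offsets so that
# one SimConfig seed governs the whole run yet stages stay decoupled.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) abort(sprintf("`%s` must be numeric and non-missing.", name))
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s.", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_simplex <- function(x, name, tol = 1e-8) {
  if (any(x < -tol)) abort(sprintf("`%s` must be non-negative.", name))
  if (abs(sum(x) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12g).", name, sum(x)))
  }
  invisible(x)
}

# 0.5 * L1 distance between rows of a matrix whose rows live on the simplex.
half_l1_dist <- function(x) {
  as.matrix(dist(x, method = "manhattan")) / 2
}

`%||%` <- rlang::`%||%`
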