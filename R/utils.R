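#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so seeded helpers do not perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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

# two-sided normal p-value for an estimate/se pair
norm_pval <- function(beta, se) {
  if (se <= 0) return(NA_real_)
  2 * stats::pnorm(-abs(beta / se))
}

# 95% normal-theory CI bounds used throughout (MREstimate invariant)
ci_bounds <- function(beta, se) c(beta - 1.96 * se, beta + 1.96 * se)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in (0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
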