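#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so library functions do not disturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
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
  set.seed(seed)
  expr
}

#' Derive a reproducible vector of child seeds from one root seed
#'
#' All randomness in a cohort flows from a single root seed: child seeds
#' (one per subject, replicate, ...) are drawn from a stream seeded with
#' the root, so the i-th child is a pure function of `(seed, n, i)`.
#'
#' @param seed integer root seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  with_seed(as.integer(seed), sample.int(.Machine$integer.max, n, replace = FALSE))
}
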