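# Small shared helpers.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded draws inside the package never disturb the session's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Frobenius-type relative difference between two complex arrays
#' @noRd
rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# derive a bounded child seed from a master seed and an index
#' @noRd
child_seed <- function(seed, index, salt = 0L) {
  # coefficients kept small so the double-precision product stays exact
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729 + salt * 97) %%
    2147483629
}
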