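# Internal helpers shared across modules.

#' Evaluate an expression with a private RNG state
#'
#' Runs `expr` after seeding the global RNG with `seed`, then restores the
#' previous RNG state so callers' random streams are untouched. All stochastic
#' operations in the package draw through this so that results are a pure
#' function of their `seed` argument.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# stopifnot() with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sub-seed derivation: fold a parent seed and a stream index into a new
# 31-bit seed, so folds / repeated draws get independent but reproducible
# streams. Plain arithmetic, kept below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(stream)) %% 2147483629)
}
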