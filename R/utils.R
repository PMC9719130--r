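#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global random
#' stream. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index; kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 1103L + 7919 * k) %% 2147483647
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
}
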