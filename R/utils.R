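#' @keywords internal
"_PACKAGE"

## NULL-default operator, used for optional config entries
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the global RNG to a known state, evaluates `expr`, and restores
#' whatever state was in place before the call, so that library code never
#' clobbers the caller's random stream.
#'
#' @param seed integer seed (must be below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

#' Derive a child seed from a run seed
#'
#' Deterministic integer mixing so that independent stages (weight
#' initialisation, dropout, k-means restarts, data generation) get distinct
#' but reproducible streams from one user-facing seed. Results stay within
#' the 32-bit integer range R requires of `set.seed`.
#'
#' @param seed base integer seed.
#' @param stream small integer identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(stream) * 2654435761) %% 2147483647
  as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  if (anyNA(x) || any(!is.finite(x))) stopf("%s contains NA or non-finite values", what)
  invisible(x)
}
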