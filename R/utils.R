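# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and a stream index
#'
#' Deterministic integer mixing (splitmix-style) so every replicate of a
#' scenario gets its own reproducible stream while staying inside R's
#' 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param index Nonnegative integer stream index (e.g. replicate number).
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @export
child_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # 64-bit-safe mixing in double arithmetic; all intermediates < 2^53
  m <- 2147483647  # 2^31 - 1, prime
  x <- (abs(master_seed) %% m)
  x <- (x * 48271 + 12345 + index * 2246822519) %% m
  x <- (x * 69621 + 7654321) %% m
  as.integer(x)
}

#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' @noRd
is_probability <- function(p) {
  is.numeric(p) && length(p) == 1L && is.finite(p) && p > 0 && p < 1
}

#' @noRd
assert_binary01 <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    stop("column '", name, "' must contain only 0/1 values", call. = FALSE)
  }
  invisible(TRUE)
}

# Moore-Penrose pseudo-inverse via SVD; used as a fallback when a
# covariance matrix is numerically singular.
#' @noRd
pseudo_inverse <- function(S, tol = 1e-10) {
  sv <- svd(S)
  pos <- sv$d > tol * max(sv$d)
  if (!any(pos)) return(matrix(0, ncol(S), nrow(S)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
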