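#' @keywords internal
"_PACKAGE"

# Stratum labels in ascending developmental order; TOP50 is the reference
# ("strong in Prep") group and is never classified for resilience.
STRATUM_LEVELS <- c("V10", "V10_25", "V25_50", "TOP50")
VULNERABLE_LEVELS <- c("V10", "V10_25", "V25_50")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_(...)
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) == 2L
}

#' Draw correlated standard-normal variates from a correlation matrix
#'
#' Cholesky-based sampler used by the cohort generator. Kept internal;
#' the matrix must be symmetric positive definite with unit diagonal.
#' @noRd
rmvn_chol <- function(n, corr) {
  p <- ncol(corr)
  L <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(L)) stop_("correlation matrix is not positive definite")
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- z %*% L
  colnames(x) <- colnames(corr)
  x
}
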