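#' @keywords internal
#' @useDynLib hblr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

## Row-wise log-sum-exp including an implicit 0 term (the reference
## coordinate contributes exp(0) to the denominator).
.lse_rows_with_zero <- function(y) {
  m <- pmax(apply(y, 1L, max), 0)
  m + log(exp(-m) + rowSums(exp(y - m)))
}

.is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

.unique_labels <- function(x, what) {
  .assert(!anyDuplicated(x), "duplicate %s labels", what)
  .assert(all(nzchar(x)), "empty %s label", what)
  invisible(x)
}

## Mills-type ratio dnorm(x)/pnorm(x), computed on the log scale so it
## survives x << 0 (where both factors underflow).
.dnorm_over_pnorm <- function(x) {
  exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))
}

## Exact inverse-CDF sampler for the N(mean, sd^2) law truncated to (0, Inf).
.rtruncnorm_pos <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- lo + stats::runif(n) * (1 - lo)
  q <- stats::qnorm(u, mean = mean, sd = sd)
  pmax(q, .Machine$double.xmin)  # guard u == lo at double precision
}
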