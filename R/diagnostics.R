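## Convergence diagnostics: split R-hat and effective sample size.

#' Split R-hat
#'
#' Potential scale reduction factor computed after splitting every chain in
#' half, so within-chain drift registers as apparent non-convergence. Values
#' near 1 indicate the chains agree in location and scale.
#'
#' @param x draws matrix, iterations x chains.
#' @return scalar R-hat, or `NA` if fewer than two (split) chains or the
#'   draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  xs <- .split_chains(x)
  m <- ncol(xs); n <- nrow(xs)
  if (m < 2L || n < 2L) return(NA_real_)
  if (stats::var(as.vector(xs)) < .Machine$double.eps) return(NA_real_)
  means <- colMeans(xs)
  vars <- apply(xs, 2L, stats::var)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w < .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted effective number of draws, pooled across split
#' chains with Geyer's initial monotone positive-sequence truncation of the
#' lagged correlations. Capped at the total number of draws.
#'
#' @param x draws matrix, iterations x chains.
#' @return scalar ESS.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  xs <- .split_chains(x)
  m <- ncol(xs); n <- nrow(xs)
  if (n < 4L) return(NA_real_)
  total <- m * n
  if (stats::var(as.vector(xs)) < .Machine$double.eps) return(NA_real_)
  max_lag <- n - 2L
  acov <- sapply(seq_len(m), function(j) {
    v <- xs[, j] - mean(xs[, j])
    stats::acf(v, lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1L, 1L]
  })
  acov <- matrix(acov, nrow = max_lag + 1L)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  means <- colMeans(xs)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(means)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  rho[1L] <- 1
  ## Geyer: sum consecutive pairs while positive, enforce monotone decrease
  s <- 0; prev_pair <- Inf; t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    s <- s + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau_hat <- max(2 * s - 1, 1 / total)
  min(total / tau_hat, total)
}

.split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 1L) return(x)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1L):n, , drop = FALSE])
}

#' Convergence report for a posterior
#'
#' Tabulates split R-hat and ESS per sampled parameter and applies the
#' configured R-hat threshold. With a single chain, R-hat is unavailable and
#' reported as `NA` with an explicit note rather than silently passing.
#'
#' @param samples a `posterior_samples` object.
#' @param sc a [sampler_config] (its `rhat_threshold` is used).
#' @return object of class `convergence_report`: data frame `per_parameter`
#'   (parameter, rhat, ess), logical `converged`, character `notes`.
#' @export
diagnostics <- function(samples, sc = samples$config) {
  .assert(inherits(samples, "posterior_samples"), "need posterior_samples")
  draws <- samples$draws                  # iterations x chains x parameters
  pars <- dimnames(draws)[[3]]
  single <- dim(draws)[2] < 2L
  per <- data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p)
      if (single) NA_real_ else split_rhat(draws[, , p]), numeric(1)),
    ess = vapply(pars, function(p) ess_basic(draws[, , p]), numeric(1)),
    row.names = NULL)
  notes <- character()
  if (single)
    notes <- c(notes, "single chain: split R-hat unavailable")
  worst <- suppressWarnings(max(per$rhat, na.rm = TRUE))
  converged <- !single && is.finite(worst) && worst < sc$rhat_threshold
  if (!single && is.finite(worst) && worst >= sc$rhat_threshold)
    notes <- c(notes, sprintf("max split R-hat %.3f exceeds threshold %.3f",
                              worst, sc$rhat_threshold))
  div_rate <- samples$divergence_rate
  if (isTRUE(div_rate > 0.1))
    notes <- c(notes, sprintf("divergent transitions: %.1f%% of draws",
                              100 * div_rate))
  structure(list(per_parameter = per, converged = converged,
                 max_rhat = if (single) NA_real_ else worst,
                 divergence_rate = div_rate, notes = notes),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence: %s (max split R-hat %s, min ESS %.0f)\n",
              if (isTRUE(x$converged)) "PASS" else "CHECK",
              if (is.na(x$max_rhat)) "NA" else sprintf("%.3f", x$max_rhat),
              suppressWarnings(min(x$per_parameter$ess, na.rm = TRUE))))
  for (n in x$notes) cat(" -", n, "\n")
  invisible(x)
}
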