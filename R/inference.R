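#' Fit the full hierarchical log-ratio model by HMC
#'
#' Samples the joint posterior of the global effects a, species magnitudes B,
#' relaxed signs (through their Gumbel latents) and the sign probability pi1
#' (plus sigma2 when the spec infers it), given log-ratio responses, a design
#' matrix and a species covariance. Chains run sequentially; chain k seeds
#' the RNG with `sc$seed + k - 1`, so results are reproducible draw-for-draw.
#'
#' @param y a `log_ratio_table` (n x (S-1)).
#' @param X a [design_matrix] (n x p, typically including an intercept).
#' @param cov a `species_covariance` ((S-1) x (S-1)).
#' @param spec a [model_spec].
#' @param sc a [sampler_config].
#' @param init `"random"` (default) draws all initial values uniformly on
#'   the unconstrained scale; `"signs"` warm-starts the sign latents at the
#'   per-taxon least-squares signs (all other coordinates stay random, and
#'   the target posterior is identical either way).
#' @return a `posterior_samples` object: `draws` (iterations x chains x
#'   parameters array on the constrained scale), `diag` (per-parameter R-hat
#'   and ESS), `divergence_rate`, `flags`, `variant`, plus the inputs' label
#'   metadata.
#' @export
fit_full <- function(y, X, cov, spec = model_spec(), sc = sampler_config(),
                     init = c("random", "signs")) {
  init <- match.arg(init)
  ctx <- .model_ctx(y, X, cov, spec, "full")
  init_signs <- if (init == "signs") estimate_signs(ctx$Y, ctx$X)
  .fit_hmc(ctx, sc, variant_tag = "full", y = y, X = X,
           init_signs = init_signs)
}

#' Two-step sign estimation by per-taxon least squares
#'
#' First step of the conditional approximation: each log-ratio coordinate is
#' regressed on the covariates by ordinary least squares, independently per
#' taxon, and the species-by-covariate sign matrix is read off the
#' coefficient signs (an exactly-zero coefficient maps to +1).
#'
#' @param y a `log_ratio_table` or n x (S-1) matrix.
#' @param X a [design_matrix] or n x p matrix of full column rank, n > p.
#' @return (S-1) x p matrix with entries in \{-1, +1\}.
#' @export
estimate_signs <- function(y, X) {
  Y <- if (inherits(y, "log_ratio_table")) y$values else as.matrix(y)
  Xm <- if (inherits(X, "design_matrix")) X$values else as.matrix(X)
  .assert(nrow(Y) == nrow(Xm), "y and X row counts differ")
  .assert(nrow(Xm) > ncol(Xm), "need more samples than covariates")
  qrx <- qr(Xm)
  .assert(qrx$rank == ncol(Xm), "design matrix is rank-deficient")
  coefs <- qr.coef(qrx, Y)                    # p x (S-1)
  signs <- t(ifelse(coefs < 0, -1, 1))        # zero maps to +1
  dimnames(signs) <- list(colnames(Y), colnames(Xm))
  signs
}

#' Fit the conditional log-ratio model
#'
#' The computationally cheaper two-step approximation: the sign matrix is
#' held fixed (from [estimate_signs], or at the simulation truth for the
#' oracle benchmark) and HMC samples only \{a, B, pi1 (, sigma2)\}; the
#' Gumbel-Softmax machinery is bypassed. The fixed signs contribute a
#' Bernoulli(pi1) term, so pi1 remains identified.
#'
#' @inheritParams fit_full
#' @param signs (S-1) x p hard sign matrix with entries in \{-1, +1\}.
#' @param variant_tag label stored with the result: `"conditional"` (default)
#'   or `"oracle"` when `signs` is the simulation truth.
#' @return a `posterior_samples` object (see [fit_full]).
#' @export
fit_conditional <- function(y, X, cov, spec = model_spec(),
                            sc = sampler_config(), signs,
                            variant_tag = "conditional") {
  ctx <- .model_ctx(y, X, cov, spec, "conditional", Gamma_fixed = signs)
  .fit_hmc(ctx, sc, variant_tag = variant_tag, y = y, X = X)
}

## Shared fitting path: run chains, transform draws, attach diagnostics.
.fit_hmc <- function(ctx, sc, variant_tag, y, X, init_signs = NULL) {
  d <- ctx$layout$d
  lpg <- function(theta) .logpost_grad(theta, ctx)
  n_keep <- sc$iterations - sc$warmup

  chains <- vector("list", sc$chains)
  div_n <- 0L; accept <- numeric(sc$chains); eps <- numeric(sc$chains)
  for (k in seq_len(sc$chains)) {
    set.seed(sc$seed + k - 1L)
    theta0 <- stats::runif(d, -2, 2)
    if (!is.null(init_signs)) {
      ## nudge g1 - g2 to the least-squares sign (magnitude 1.5, small
      ## enough that weakly identified signs can still flip during warmup)
      L <- ctx$layout
      theta0[L$g1] <- 0.75 * as.vector(init_signs)
      theta0[L$g2] <- -0.75 * as.vector(init_signs)
    }
    res <- .hmc_chain(lpg, theta0, sc$iterations, sc$warmup,
                      sc$target_accept, sc$max_leapfrog, sc$traj_length)
    chains[[k]] <- res$draws
    div_n <- div_n + sum(res$divergent)
    accept[k] <- res$accept_rate
    eps[k] <- res$eps
  }

  pn <- .param_names(ctx)
  draws <- array(NA_real_, c(n_keep, sc$chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (k in seq_len(sc$chains))
    draws[, k, ] <- .constrain_draws(chains[[k]], ctx)

  div_rate <- div_n / (n_keep * sc$chains)
  per <- data.frame(
    parameter = pn,
    rhat = vapply(pn, function(p)
      if (sc$chains < 2L) NA_real_ else split_rhat(draws[, , p]), numeric(1)),
    ess = vapply(pn, function(p) ess_basic(draws[, , p]), numeric(1)),
    row.names = NULL)
  flags <- character()
  if (div_rate > 0.1)
    flags <- c(flags, sprintf("divergence-dominated run: %.1f%% divergent",
                              100 * div_rate))
  worst <- suppressWarnings(max(per$rhat, na.rm = TRUE))
  if (sc$chains >= 2L && is.finite(worst) && worst >= sc$rhat_threshold)
    flags <- c(flags, sprintf("max split R-hat %.3f >= %.3f",
                              worst, sc$rhat_threshold))
  for (f in flags) warning(f, call. = FALSE)

  taxa <- if (inherits(y, "log_ratio_table")) y$taxon_ids
          else colnames(ctx$Y) %||% paste0("taxon", seq_len(ctx$K))
  covs <- if (inherits(X, "design_matrix")) X$covariate_names
          else colnames(ctx$X) %||% paste0("x", seq_len(ctx$q))
  structure(list(draws = draws, diag = per, divergence_rate = div_rate,
                 accept_rate = accept, step_size = eps, flags = flags,
                 variant = variant_tag, config = sc, spec = ctx$spec,
                 taxon_ids = taxa, covariate_names = covs,
                 K = ctx$K, q = ctx$q,
                 signs_fixed = if (ctx$variant == "conditional") ctx$Gamma),
            class = "posterior_samples")
}

.param_names <- function(ctx) {
  K <- ctx$K; q <- ctx$q
  mat_names <- function(stem)
    as.vector(outer(seq_len(K), seq_len(q),
                    function(s, j) sprintf("%s[%d,%d]", stem, s, j)))
  pn <- c(sprintf("a[%d]", seq_len(q)), mat_names("beta"))
  if (ctx$variant == "full") pn <- c(pn, mat_names("delta"))
  pn <- c(pn, "pi1")
  if (ctx$spec$infer_sigma2) pn <- c(pn, "sigma2")
  pn
}

.constrain_draws <- function(mat, ctx) {
  L <- ctx$layout
  out <- cbind(exp(mat[, L$ta, drop = FALSE]),
               exp(mat[, L$tb, drop = FALSE]))
  if (ctx$variant == "full") {
    eta <- (mat[, L$lambda] + mat[, L$g1, drop = FALSE] -
              mat[, L$g2, drop = FALSE]) / ctx$spec$tau
    out <- cbind(out, stats::plogis(eta))
  }
  out <- cbind(out, stats::plogis(mat[, L$lambda]))
  if (ctx$spec$infer_sigma2) out <- cbind(out, exp(mat[, L$ts]))
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples (%s model): %d draws x %d chains, %d parameters\n",
    x$variant, dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3]))
  worst <- suppressWarnings(max(x$diag$rhat, na.rm = TRUE))
  cat(sprintf("  max split R-hat: %s; divergence rate: %.2f%%\n",
              if (is.finite(worst)) sprintf("%.3f", worst) else "NA",
              100 * x$divergence_rate))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Posterior summaries
#'
#' `posterior_summary` tabulates mean, sd, central 95% interval, R-hat and
#' ESS per parameter. `global_effects_summary` restricts to the global
#' effects a_j with covariate labels. `signed_effects` returns the
#' (S-1) x p matrix of posterior means of gamma * beta — the signed
#' species-specific effects (for the full model, gamma = 2 delta - 1 per
#' draw; for conditional fits the fixed signs are used). `sign_calls`
#' thresholds the posterior mean of delta at 1/2 for a hard sign decision.
#'
#' @param samples a `posterior_samples` object.
#' @return data frame or matrix as described.
#' @export
posterior_summary <- function(samples) {
  draws <- samples$draws
  pn <- dimnames(draws)[[3]]
  flat <- function(p) as.vector(draws[, , p])
  out <- data.frame(
    parameter = pn,
    mean = vapply(pn, function(p) mean(flat(p)), numeric(1)),
    sd = vapply(pn, function(p) stats::sd(flat(p)), numeric(1)),
    q2.5 = vapply(pn, function(p) stats::quantile(flat(p), 0.025), numeric(1)),
    q97.5 = vapply(pn, function(p) stats::quantile(flat(p), 0.975), numeric(1)),
    row.names = NULL)
  merge(out, samples$diag, by = "parameter", sort = FALSE)
}

#' @rdname posterior_summary
#' @export
global_effects_summary <- function(samples) {
  s <- posterior_summary(samples)
  s <- s[grepl("^a\\[", s$parameter), , drop = FALSE]
  s$covariate <- samples$covariate_names
  s[, c("covariate", "mean", "sd", "q2.5", "q97.5", "rhat", "ess")]
}

#' @rdname posterior_summary
#' @export
signed_effects <- function(samples) {
  K <- samples$K; q <- samples$q
  out <- matrix(NA_real_, K, q,
                dimnames = list(samples$taxon_ids, samples$covariate_names))
  for (j in seq_len(q)) for (s in seq_len(K)) {
    b <- as.vector(samples$draws[, , sprintf("beta[%d,%d]", s, j)])
    g <- if (samples$variant == "full") {
      2 * as.vector(samples$draws[, , sprintf("delta[%d,%d]", s, j)]) - 1
    } else samples$signs_fixed[s, j]
    out[s, j] <- mean(g * b)
  }
  out
}

#' @rdname posterior_summary
#' @export
sign_calls <- function(samples) {
  .assert(samples$variant == "full", "sign_calls needs a full-model fit")
  K <- samples$K; q <- samples$q
  out <- matrix(NA_real_, K, q,
                dimnames = list(samples$taxon_ids, samples$covariate_names))
  for (j in seq_len(q)) for (s in seq_len(K))
    out[s, j] <- mean(samples$draws[, , sprintf("delta[%d,%d]", s, j)])
  .hard_sign(out)
}

#' Export posterior draws and summaries
#'
#' `write_posterior` writes tidy long format (chain, iteration, parameter,
#' value); `write_posterior_summary` writes the [posterior_summary] table.
#' Both are plain TSV.
#'
#' @param samples a `posterior_samples` object.
#' @param path output file path.
#' @export
write_posterior <- function(samples, path) {
  draws <- samples$draws
  dd <- dim(draws)
  long <- data.frame(
    chain = rep(rep(seq_len(dd[2]), each = dd[1]), times = dd[3]),
    iteration = rep(seq_len(dd[1]), times = dd[2] * dd[3]),
    parameter = rep(dimnames(draws)[[3]], each = dd[1] * dd[2]),
    value = as.vector(draws))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_posterior
#' @export
write_posterior_summary <- function(samples, path) {
  utils::write.table(posterior_summary(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
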