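test_that("estimate_signs recovers noiseless signs exactly", {
  set.seed(41)
  n <- 50; K <- 6; q <- 3
  X <- cbind(1, matrix(rnorm(n * (q - 1)), n))
  Gamma <- matrix(sample(c(-1, 1), K * q, replace = TRUE), K, q)
  B <- matrix(runif(K * q, 0.5, 2), K, q)
  Y <- X %*% t(Gamma * B)                   # zero-noise responses
  expect_identical(unname(estimate_signs(Y, X)), Gamma)
})

test_that("estimate_signs maps zero coefficients to +1 and is OLS-equivariant", {
  set.seed(43)
  n <- 30
  X <- cbind(1, rnorm(n))
  Y <- cbind(X %*% c(2, 0), X %*% c(-1, 0.7))   # exact zero slope in col 1
  signs <- estimate_signs(Y, X)
  expect_equal(unname(signs[1, ]), c(1, 1))
  expect_equal(unname(signs[2, ]), c(-1, 1))
  Xneg <- X; Xneg[, 2] <- -X[, 2]
  signs2 <- estimate_signs(Y, Xneg)
  expect_equal(signs2[, 2], -signs[, 2])
  expect_equal(signs2[, 1], signs[, 1])
  expect_error(estimate_signs(Y, cbind(X, X[, 2])), "rank")
})

test_that("split R-hat and ESS match their formula oracles", {
  set.seed(47)
  # null case: i.i.d. Gaussian chains
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(x), 1.01)
  expect_equal(split_rhat(x), oracle_split_rhat(x), tolerance = 1e-12)
  # shifted chains must be flagged
  xs <- x + rep(c(0, 0, 2, 2), each = 1000)
  expect_gt(split_rhat(xs), 1.1)
  expect_equal(split_rhat(xs), oracle_split_rhat(xs), tolerance = 1e-12)
  # ESS bounded by total draws; heavy autocorrelation shrinks it
  expect_lte(ess_basic(x), 4000)
  ar <- matrix(0, 500, 2)
  for (j in 1:2) ar[, j] <- as.vector(arima.sim(list(ar = 0.9), 500))
  expect_lt(ess_basic(ar), 0.5 * 1000)
})

test_that("HMC fits are reproducible, respect supports, and carry diagnostics", {
  tr <- tiny_truth(seed = 51)
  spec <- model_spec(sigma2 = 0.1)
  sc <- quick_sc(seed = 8)
  fit1 <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov, spec, sc))
  fit2 <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov, spec, sc))
  expect_identical(fit1$draws, fit2$draws)      # same seed -> same draws

  draws <- fit1$draws
  pn <- dimnames(draws)[[3]]
  expect_true(all(draws[, , grep("^beta", pn)] > 0))
  expect_true(all(draws[, , grep("^a\\[", pn)] >= 0))
  d <- draws[, , grep("^delta", pn)]
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(draws[, , "pi1"] > 0 & draws[, , "pi1"] < 1))
  expect_true(all(is.finite(fit1$diag$rhat)))
  expect_true(all(fit1$diag$ess <= prod(dim(draws)[1:2])))

  rep <- diagnostics(fit1, sc)
  expect_s3_class(rep, "convergence_report")
  expect_equal(nrow(rep$per_parameter), length(pn))

  # single chain: R-hat unavailable, reported as such
  sc1 <- quick_sc(seed = 8, chains = 1, iterations = 200)
  fit_s <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov, spec, sc1))
  rep_s <- diagnostics(fit_s, sc1)
  expect_true(all(is.na(rep_s$per_parameter$rhat)))
  expect_match(paste(rep_s$notes, collapse = " "), "single chain")
})

test_that("conditional fit holds signs fixed and samples the rest", {
  tr <- tiny_truth(seed = 53)
  spec <- model_spec(sigma2 = 0.1)
  signs <- estimate_signs(tr$y, tr$X)
  fit <- suppressWarnings(
    fit_conditional(tr$y, tr$X, tr$cov, spec, quick_sc(seed = 9), signs))
  expect_identical(fit$variant, "conditional")
  expect_false(any(grepl("^delta", dimnames(fit$draws)[[3]])))
  expect_identical(fit$signs_fixed, signs)
  fit2 <- suppressWarnings(
    fit_conditional(tr$y, tr$X, tr$cov, spec, quick_sc(seed = 9), signs))
  expect_identical(fit$draws, fit2$draws)
  expect_error(
    fit_conditional(tr$y, tr$X, tr$cov, spec, quick_sc(), signs * 0.5),
    "-1 or \\+1")
})

test_that("posterior interval for a global effect narrows with sample size", {
  widths <- sapply(c(50, 200), function(n) {
    cfg <- simulation_config(n = n, S = 4, p = 1, a = c(0, 0.8),
                             sigma2 = 0.1, seed = 59, use_tree = FALSE)
    tr <- simulate_dataset(cfg)
    fit <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov,
                                     model_spec(sigma2 = 0.1),
                                     quick_sc(seed = 10, iterations = 800)))
    g <- global_effects_summary(fit)
    g$q97.5[2] - g$q2.5[2]
  })
  expect_lt(widths[2], widths[1])
})

test_that("summaries and exports are consistent with the raw draws", {
  tr <- tiny_truth(seed = 61)
  fit <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov,
                                   model_spec(sigma2 = 0.1),
                                   quick_sc(seed = 11, iterations = 400)))
  s <- posterior_summary(fit)
  expect_equal(s$mean[s$parameter == "pi1"], mean(fit$draws[, , "pi1"]))
  g <- global_effects_summary(fit)
  expect_identical(g$covariate, fit$covariate_names)

  # signed effects equal mean over draws of gamma * beta, recomputed here
  eff <- signed_effects(fit)
  b <- as.vector(fit$draws[, , "beta[2,1]"])
  del <- as.vector(fit$draws[, , "delta[2,1]"])
  expect_equal(eff[2, 1], mean((2 * del - 1) * b))

  calls <- sign_calls(fit)
  expect_true(all(calls %in% c(-1, 1)))

  dir <- withr::local_tempdir()
  write_posterior(fit, file.path(dir, "post.tsv"))
  long <- read.table(file.path(dir, "post.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(long), prod(dim(fit$draws)))
  expect_equal(mean(long$value[long$parameter == "pi1"]),
               mean(fit$draws[, , "pi1"]))
  write_posterior_summary(fit, file.path(dir, "summary.tsv"))
  s2 <- read.table(file.path(dir, "summary.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(s2), nrow(s))
})

test_that("sigma2 can be inferred under its half-Gaussian hyperprior", {
  tr <- tiny_truth(seed = 67)
  fit <- suppressWarnings(fit_full(tr$y, tr$X, tr$cov,
                                   model_spec(sigma2 = "infer"),
                                   quick_sc(seed = 12, iterations = 400)))
  s2 <- fit$draws[, , "sigma2"]
  expect_true(all(s2 > 0))
})
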