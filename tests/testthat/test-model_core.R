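test_that("gumbel_softmax_delta matches direct evaluation and limits", {
  # symmetric arguments: exactly 1/2 at any temperature
  for (tau in c(0.01, 0.5, 3))
    expect_equal(gumbel_softmax_delta(0.5, 1.3, 1.3, tau), 0.5)
  # frozen value computed by independent arithmetic of the two-class softmax
  expect_equal(gumbel_softmax_delta(0.7, 0.1, -0.2, 1), 0.7590170,
               tolerance = 1e-6)
  # tau -> 0 collapses to the argmax indicator, without overflow
  expect_equal(gumbel_softmax_delta(0.6, 0.5, -0.5, 1e-8), 1)
  expect_equal(gumbel_softmax_delta(0.4, -2, 2, 1e-8), 0)
  expect_error(gumbel_softmax_delta(0.5, 0, 0, 0), "tau")
  expect_error(gumbel_softmax_delta(1, 0, 0, 1), "pi1")
})

test_that("relaxed draws recover the exact categorical law at small tau", {
  set.seed(101)
  for (pi1 in c(0.2, 0.5, 0.8)) {
    n <- 10000
    g1 <- -log(-log(runif(n)))
    g2 <- -log(-log(runif(n)))
    delta <- gumbel_softmax_delta(pi1, g1, g2, tau = 0.01)
    phat <- mean(delta > 0.5)
    se <- sqrt(pi1 * (1 - pi1) / n)
    expect_lt(abs(phat - pi1), 3 * se)
  }
})

test_that("gamma_from_delta is the affine map with the stated endpoints", {
  expect_equal(gamma_from_delta(1), 1)
  expect_equal(gamma_from_delta(0), -1)
  expect_equal(gamma_from_delta(0.5), 0)
  expect_equal(gamma_from_delta(c(0.25, 0.75)), c(-0.5, 0.5))
  expect_error(gamma_from_delta(1.2), "delta")
})

test_that("linear_predictor computes (Gamma * B) x with shape checks", {
  G <- matrix(c(1, -1), 2, 1); B <- matrix(c(2, 3), 2, 1)
  expect_equal(linear_predictor(G, B, 0.5), c(1, -1.5))
  expect_equal(linear_predictor(G, matrix(0, 2, 1), 0.5), c(0, 0))
  expect_equal(linear_predictor(-G, B, 0.5), -linear_predictor(G, B, 0.5))
  X <- matrix(c(1, 2), 2, 1)
  expect_equal(linear_predictor(G, B, X),
               rbind(c(2, -3), c(4, -6)))
  expect_error(linear_predictor(G, B, c(1, 2)), "length")
})

test_that("log_joint_density matches the term-wise oracle on random draws", {
  set.seed(55)
  tr <- tiny_truth()
  spec <- model_spec(sigma2 = 0.1)
  K <- ncol(tr$y$values); q <- ncol(tr$X$values)
  # ridge-stabilised covariance, as used internally
  V <- tr$cov$values + diag(1e-8 * mean(diag(tr$cov$values)), K)
  for (i in 1:10) {
    params <- list(a = rexp(q), B = matrix(rexp(K * q), K, q),
                   g1 = matrix(rnorm(K * q), K, q),
                   g_neg1 = matrix(rnorm(K * q), K, q),
                   pi1 = runif(1, 0.1, 0.9))
    lp <- log_joint_density(params, tr$y, tr$X, tr$cov, spec, "full")
    expect_equal(lp, oracle_log_joint_full(params, tr$y$values, tr$X$values,
                                           V, spec),
                 tolerance = 1e-8)
  }
})

test_that("one-dimensional MVN term reduces to the univariate Gaussian", {
  set.seed(66)
  n <- 8
  y <- log_ratio_table(matrix(rnorm(n), n, 1), taxon_ids = "A",
                       reference_taxon = "B")
  X <- design_matrix(matrix(rnorm(n), n, 1), "x1")
  v <- 0.7
  cov1 <- species_covariance(matrix(v, 1, 1), "A")
  spec <- model_spec(sigma2 = 0.1)
  params <- list(a = 0.5, B = matrix(0.4), g1 = matrix(0.3),
                 g_neg1 = matrix(-0.1), pi1 = 0.5)
  lp <- log_joint_density(params, y, X, cov1, spec, "full")
  delta <- gumbel_softmax_delta(0.5, 0.3, -0.1, spec$tau)
  mu <- (2 * delta - 1) * 0.4 * X$values[, 1]
  vr <- v * (1 + 1e-8)  # internal ridge
  ll_uni <- sum(dnorm(y$values[, 1], mu, sqrt(vr), log = TRUE))
  # non-likelihood terms, coded independently
  lp_rest <- oracle_truncnorm_logpdf(0.4, 0.5, sqrt(0.1)) +
    oracle_truncnorm_logpdf(0.5, 0, 1) + dbeta(0.5, 1, 1, log = TRUE) +
    oracle_gumbel_logpdf(0.3) + oracle_gumbel_logpdf(-0.1)
  expect_equal(lp, ll_uni + lp_rest, tolerance = 1e-9)
  # doubling c rescales the Gaussian term by the closed form
  cov2 <- species_covariance(matrix(2 * v, 1, 1), "A", scale_c = 2)
  lp2 <- log_joint_density(params, y, X, cov2, spec, "full")
  ll2_uni <- sum(dnorm(y$values[, 1], mu, sqrt(2 * vr), log = TRUE))
  expect_equal(lp2 - lp, ll2_uni - ll_uni, tolerance = 1e-9)
})

test_that("support violations yield -Inf density", {
  tr <- tiny_truth()
  spec <- model_spec(sigma2 = 0.1)
  K <- ncol(tr$y$values); q <- ncol(tr$X$values)
  ok <- list(a = rep(0.5, q), B = matrix(1, K, q),
             g1 = matrix(0, K, q), g_neg1 = matrix(0, K, q), pi1 = 0.5)
  bad_b <- ok; bad_b$B[1, 1] <- -0.1
  expect_identical(log_joint_density(bad_b, tr$y, tr$X, tr$cov, spec), -Inf)
  bad_b0 <- ok; bad_b0$B[2, 1] <- 0
  expect_identical(log_joint_density(bad_b0, tr$y, tr$X, tr$cov, spec), -Inf)
  bad_a <- ok; bad_a$a[1] <- -0.2
  expect_identical(log_joint_density(bad_a, tr$y, tr$X, tr$cov, spec), -Inf)
})

test_that("sampler gradient passes a finite-difference check (both variants)", {
  set.seed(77)
  tr <- tiny_truth()
  for (variant in c("full", "conditional")) {
    signs <- if (variant == "conditional") estimate_signs(tr$y, tr$X)
    ctx <- hblr:::.model_ctx(tr$y, tr$X, tr$cov, model_spec(sigma2 = 0.1),
                             variant, signs)
    for (i in 1:5) {
      theta <- runif(ctx$layout$d, -1.5, 1.5)
      g <- hblr:::.logpost_grad(theta, ctx)
      num <- vapply(seq_along(theta), function(k) {
        h <- 1e-6; tp <- theta; tm <- theta
        tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
        (hblr:::.logpost_grad(tp, ctx)$lp -
           hblr:::.logpost_grad(tm, ctx)$lp) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(num - g$grad) / (abs(g$grad) + 1)), 1e-4)
    }
  }
})

test_that("compiled gradient equals the pure-R reference implementation", {
  set.seed(88)
  tr <- tiny_truth()
  grid <- expand.grid(variant = c("full", "conditional"),
                      infer = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    spec <- if (grid$infer[r]) model_spec(sigma2 = "infer") else model_spec()
    signs <- if (grid$variant[r] == "conditional") estimate_signs(tr$y, tr$X)
    ctx <- hblr:::.model_ctx(tr$y, tr$X, tr$cov, spec, grid$variant[r], signs)
    for (i in 1:4) {
      theta <- runif(ctx$layout$d, -1.5, 1.5)
      cpp <- hblr:::.logpost_grad(theta, ctx)
      ref <- hblr:::.logpost_grad_r(theta, ctx)
      expect_equal(cpp$lp, ref$lp, tolerance = 1e-10)
      expect_equal(cpp$grad, ref$grad, tolerance = 1e-8)
    }
  }
})

test_that("unconstrained log posterior = constrained density + log Jacobians", {
  set.seed(99)
  tr <- tiny_truth()
  spec <- model_spec(sigma2 = 0.1)
  ctx <- hblr:::.model_ctx(tr$y, tr$X, tr$cov, spec, "full")
  theta <- runif(ctx$layout$d, -1, 1)
  st <- hblr:::.logpost_grad(theta, ctx)
  params <- hblr:::.constrain(theta, ctx)
  lp_c <- log_joint_density(params, tr$y, tr$X, tr$cov, spec, "full")
  L <- ctx$layout
  jac <- sum(theta[L$ta]) + sum(theta[L$tb]) +
    log(params$pi1) + log(1 - params$pi1)
  expect_equal(st$lp, lp_c + jac, tolerance = 1e-8)
})

test_that("model_spec round-trips through its flat config file", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "spec.cfg")
  s1 <- model_spec(sigma2 = 0.25, tau = 0.05, pi1_alpha = 2, pi1_beta = 3,
                   scale_c = 1.5)
  write_model_spec(s1, f)
  expect_equal(read_model_spec(f), s1)
  s2 <- model_spec(sigma2 = "infer")
  write_model_spec(s2, f)
  expect_true(read_model_spec(f)$infer_sigma2)
  expect_error(model_spec(tau = 0), "tau")
  expect_error(model_spec(sigma2 = -1), "sigma2")
})
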