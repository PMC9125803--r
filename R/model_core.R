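## Core densities of the hierarchical log-ratio regression.
##
## Likelihood:  y_i ~ MVN((Gamma (*) B) x_i, c Sigma)    (rows of Y)
## Hierarchy:   beta_(s,j) ~ N+(a_j, sigma2)   a_j ~ N+(0, 1)
## Signs:       gamma = 2 delta - 1, delta a Gumbel-Softmax relaxation of
##              Bernoulli(pi1) at temperature tau;  pi1 ~ Beta(alpha, beta).
## The relaxation keeps the joint density differentiable, so the whole
## posterior is sampled by gradient-based HMC.

#' Gumbel-Softmax relaxed Bernoulli draw
#'
#' Two-class Gumbel-Softmax: given the positive-sign probability `pi1`, two
#' Gumbel(0, 1) variates `g1`, `g_neg1` and a temperature `tau`, returns
#' delta = softmax((log pi1 + g1) / tau, (log(1 - pi1) + g_neg1) / tau)[1].
#' As tau -> 0 the relaxation collapses to the exact categorical draw
#' (argmax); the computation shifts exponents so no overflow occurs at small
#' tau. All arguments may be arrays of a common shape.
#'
#' @param pi1 probability of the +1 sign class, strictly inside (0, 1).
#' @param g1,g_neg1 Gumbel(0, 1) variates for the +1 and -1 classes.
#' @param tau temperature > 0.
#' @return delta in (0, 1), same shape as the inputs.
#' @export
gumbel_softmax_delta <- function(pi1, g1, g_neg1, tau) {
  .assert(is.numeric(tau) && length(tau) == 1L && tau > 0, "tau must be > 0")
  .assert(all(pi1 > 0 & pi1 < 1), "pi1 must be strictly inside (0, 1)")
  .assert(all(is.finite(g1)) && all(is.finite(g_neg1)), "Gumbel draws must be finite")
  ## softmax of two logits == logistic of their difference (shift-stable)
  stats::plogis((log(pi1) + g1 - log1p(-pi1) - g_neg1) / tau)
}

#' @rdname gumbel_softmax_delta
#' @param delta relaxed sign in [0, 1].
#' @return `gamma_from_delta`: the signed value 2 * delta - 1 in [-1, 1].
#' @export
gamma_from_delta <- function(delta) {
  .assert(all(delta >= 0 & delta <= 1), "delta must lie in [0, 1]")
  2 * delta - 1
}

## Hard sign from a relaxed delta: threshold at 1/2, ties to +1.
.hard_sign <- function(delta) ifelse(delta >= 0.5, 1, -1)

#' Linear predictor of the log-ratio means
#'
#' mu_i = (Gamma (*) B) x_i, where (*) is the elementwise product of the sign
#' matrix and the positive magnitude matrix. Vectorised over samples: with X
#' an n x p design, returns the n x (S-1) matrix of means.
#'
#' @param Gamma (S-1) x p sign matrix (entries in [-1, 1]; hard signs or a
#'   relaxed state).
#' @param B (S-1) x p positive magnitude matrix.
#' @param x length-p covariate vector, or an n x p design matrix.
#' @return length-(S-1) mean vector, or an n x (S-1) matrix of means.
#' @export
linear_predictor <- function(Gamma, B, x) {
  Gamma <- as.matrix(Gamma); B <- as.matrix(B)
  .assert(all(dim(Gamma) == dim(B)), "Gamma and B shapes differ")
  M <- Gamma * B
  if (is.matrix(x)) {
    .assert(ncol(x) == ncol(M), "design has %d columns, model expects %d",
            ncol(x), ncol(M))
    x %*% t(M)
  } else {
    .assert(length(x) == ncol(M), "covariate vector has length %d, expected %d",
            length(x), ncol(M))
    drop(M %*% x)
  }
}

#' Joint log-density of the hierarchical log-ratio model
#'
#' Evaluates, on the constrained scale and up to additive constants that do
#' not involve parameters, the sum of: the MVN log-likelihood of every sample
#' with mean from [linear_predictor] and covariance c Sigma; the truncated
#' Gaussian N+(a_j, sigma2) log-prior of every magnitude (including the
#' a_j-dependent truncation normaliser 1 / Phi(a_j / sigma)); the N+(0, 1)
#' log-prior of every global effect; the Beta log-prior of pi1; and, for the
#' full variant, the Gumbel(0, 1) log-densities of the latent sign variables.
#' For the conditional variant the fixed hard signs contribute their
#' Bernoulli(pi1) log-mass instead.
#'
#' @param params named list with elements `a` (length-p, >= 0), `B`
#'   ((S-1) x p, > 0), `pi1` (scalar in (0, 1)); for the full variant `g1`,
#'   `g_neg1` ((S-1) x p Gumbel latents); for the conditional variant `Gamma`
#'   ((S-1) x p hard signs); optionally `sigma2` when the spec infers it.
#' @param y a `log_ratio_table` (or plain n x (S-1) matrix).
#' @param design a [design_matrix] (or plain n x p matrix).
#' @param cov a `species_covariance`.
#' @param spec a [model_spec].
#' @param variant `"full"` or `"conditional"`.
#' @return a finite scalar log-density.
#' @export
log_joint_density <- function(params, y, design, cov, spec,
                              variant = c("full", "conditional")) {
  variant <- match.arg(variant)
  Y <- if (inherits(y, "log_ratio_table")) y$values else as.matrix(y)
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  fac <- .cov_factor(cov)
  K <- ncol(Y); q <- ncol(X); n <- nrow(Y)
  a <- params$a; B <- as.matrix(params$B); pi1 <- params$pi1
  sigma2 <- if (spec$infer_sigma2) params$sigma2 else spec$sigma2
  .assert(length(a) == q && all(dim(B) == c(K, q)), "parameter shape mismatch")
  if (any(B <= 0) || any(a < 0) || is.null(sigma2) || sigma2 <= 0) return(-Inf)
  sigma <- sqrt(sigma2)

  if (variant == "full") {
    delta <- gumbel_softmax_delta(pi1, params$g1, params$g_neg1, spec$tau)
    Gamma <- gamma_from_delta(delta)
  } else {
    Gamma <- as.matrix(params$Gamma)
    .assert(all(Gamma %in% c(-1, 1)), "conditional variant needs hard signs")
  }

  R <- Y - linear_predictor(Gamma, B, X)
  ll <- -0.5 * sum((R %*% fac$omega) * R) - n / 2 * fac$logdet -
    n * K / 2 * log(2 * pi)

  arow <- matrix(a, K, q, byrow = TRUE)
  lp_beta <- sum(stats::dnorm(B, arow, sigma, log = TRUE)) -
    K * sum(stats::pnorm(a / sigma, log.p = TRUE))
  lp_a <- sum(stats::dnorm(a, 0, 1, log = TRUE)) + q * log(2)
  lp_pi <- stats::dbeta(pi1, spec$pi1_alpha, spec$pi1_beta, log = TRUE)

  lp_lat <- if (variant == "full") {
    sum(-params$g1 - exp(-params$g1)) + sum(-params$g_neg1 - exp(-params$g_neg1))
  } else {
    sum(Gamma == 1) * log(pi1) + sum(Gamma == -1) * log1p(-pi1)
  }
  lp_s2 <- if (spec$infer_sigma2) {
    stats::dnorm(sigma2, 0, 1, log = TRUE) + log(2)
  } else 0

  ll + lp_beta + lp_a + lp_pi + lp_lat + lp_s2
}

## ---------------------------------------------------------------------------
## Unconstrained-scale posterior and analytic gradient for the HMC sampler.
##
## Full variant parameter vector:
##   [ta (q)] [tb (K*q)] [g1 (K*q)] [g2 (K*q)] [lambda] ([ts])
## with a = exp(ta), B = exp(tb), pi1 = plogis(lambda), sigma2 = exp(ts).
## Conditional variant drops g1/g2 (signs fixed):
##   [ta (q)] [tb (K*q)] [lambda] ([ts])
## Log-Jacobians of the transforms are included so that HMC targets the
## correct posterior on the unconstrained space.

.par_layout <- function(K, q, variant, infer_sigma2) {
  kq <- K * q
  if (variant == "full") {
    idx <- list(ta = 1:q, tb = q + 1:kq, g1 = q + kq + 1:kq,
                g2 = q + 2 * kq + 1:kq, lambda = q + 3 * kq + 1L)
    d <- q + 3 * kq + 1L
  } else {
    idx <- list(ta = 1:q, tb = q + 1:kq, lambda = q + kq + 1L)
    d <- q + kq + 1L
  }
  if (infer_sigma2) { idx$ts <- d + 1L; d <- d + 1L }
  c(idx, list(d = d, K = K, q = q))
}

## Shared data context precomputed once per fit.
.model_ctx <- function(y, design, cov, spec, variant, Gamma_fixed = NULL) {
  Y <- if (inherits(y, "log_ratio_table")) y$values else as.matrix(y)
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  .assert(nrow(Y) == nrow(X), "y and design row counts differ")
  fac <- .cov_factor(cov)
  K <- ncol(Y); q <- ncol(X)
  if (variant == "conditional") {
    Gamma_fixed <- as.matrix(Gamma_fixed)
    .assert(all(dim(Gamma_fixed) == c(K, q)), "sign matrix shape mismatch")
    .assert(all(Gamma_fixed %in% c(-1, 1)), "signs must be -1 or +1")
  }
  list(Y = Y, X = X, omega = fac$omega, logdet = fac$logdet,
       n = nrow(Y), K = K, q = q, spec = spec, variant = variant,
       Gamma = Gamma_fixed, layout = .par_layout(K, q, variant, spec$infer_sigma2))
}

## Returns list(lp = scalar, grad = d-vector); -Inf lp on numerical failure.
## Dispatches to the compiled implementation; the pure-R twin below is the
## reference the test suite cross-checks it against.
.logpost_grad <- function(theta, ctx) {
  if (isTRUE(getOption("hblr.use_r_gradient"))) return(.logpost_grad_r(theta, ctx))
  .logpost_grad_cpp(theta, ctx$Y, ctx$X, ctx$omega, ctx$logdet,
                    ctx$spec$tau, ctx$spec$pi1_alpha, ctx$spec$pi1_beta,
                    if (ctx$spec$infer_sigma2) -1 else ctx$spec$sigma2,
                    ctx$spec$infer_sigma2, ctx$variant == "full",
                    if (ctx$variant == "full") matrix(0, 0, 0) else ctx$Gamma)
}

.logpost_grad_r <- function(theta, ctx) {
  L <- ctx$layout; spec <- ctx$spec
  K <- ctx$K; q <- ctx$q; n <- ctx$n
  ta <- theta[L$ta]; tb <- theta[L$tb]; lambda <- theta[L$lambda]
  a <- exp(ta)
  B <- matrix(exp(tb), K, q)
  pi1 <- stats::plogis(lambda)
  if (spec$infer_sigma2) { sigma2 <- exp(theta[L$ts]) } else sigma2 <- spec$sigma2
  sigma <- sqrt(sigma2)
  if (!all(is.finite(a)) || !all(is.finite(B)) || !is.finite(sigma2))
    return(list(lp = -Inf, grad = rep(0, L$d)))

  if (ctx$variant == "full") {
    g1 <- matrix(theta[L$g1], K, q)
    g2 <- matrix(theta[L$g2], K, q)
    eta <- (lambda + g1 - g2) / spec$tau
    delta <- stats::plogis(eta)
    Gamma <- 2 * delta - 1
  } else {
    Gamma <- ctx$Gamma
  }

  M <- Gamma * B
  R <- ctx$Y - ctx$X %*% t(M)
  RO <- R %*% ctx$omega
  ll <- -0.5 * sum(RO * R) - n / 2 * ctx$logdet - n * K / 2 * log(2 * pi)
  dM <- crossprod(RO, ctx$X)                     # d ll / d M, K x q

  arow <- matrix(a, K, q, byrow = TRUE)
  z <- a / sigma
  lp <- ll +
    sum(stats::dnorm(B, arow, sigma, log = TRUE)) -
    K * sum(stats::pnorm(z, log.p = TRUE)) +
    sum(stats::dnorm(a, 0, 1, log = TRUE)) + q * log(2) +
    stats::dbeta(pi1, spec$pi1_alpha, spec$pi1_beta, log = TRUE) +
    log(pi1) + log1p(-pi1) +                     # logit Jacobian
    sum(ta) + sum(tb)                            # log Jacobians of exp

  dB <- dM * Gamma - (B - arow) / sigma2
  hz <- .dnorm_over_pnorm(z)
  da <- colSums(B - arow) / sigma2 - K * hz / sigma - a
  dlambda <- (spec$pi1_alpha - 1) * (1 - pi1) - (spec$pi1_beta - 1) * pi1 +
    (1 - 2 * pi1)

  grad <- numeric(L$d)
  if (ctx$variant == "full") {
    lp <- lp + sum(-g1 - exp(-g1)) + sum(-g2 - exp(-g2))
    w <- (2 * dM * B) * delta * (1 - delta) / spec$tau   # d ll / d eta pieces
    grad[L$g1] <- w - 1 + exp(-g1)
    grad[L$g2] <- -w - 1 + exp(-g2)
    dlambda <- dlambda + sum(w)
  } else {
    npos <- sum(Gamma == 1); nneg <- K * q - npos
    lp <- lp + npos * log(pi1) + nneg * log1p(-pi1)
    dlambda <- dlambda + npos * (1 - pi1) - nneg * pi1
  }

  if (spec$infer_sigma2) {
    lp <- lp + stats::dnorm(sigma2, 0, 1, log = TRUE) + log(2) + theta[L$ts]
    dsigma <- sum(-1 / sigma + (B - arow)^2 / sigma^3) + sum(K * hz * a / sigma2)
    grad[L$ts] <- dsigma * sigma / 2 - sigma2^2 + 1
  }

  grad[L$ta] <- a * da + 1
  grad[L$tb] <- as.vector(B * dB + 1)
  grad[L$lambda] <- dlambda
  if (!is.finite(lp)) return(list(lp = -Inf, grad = rep(0, L$d)))
  list(lp = lp, grad = grad)
}

## Map an unconstrained vector to the constrained parameter list.
.constrain <- function(theta, ctx) {
  L <- ctx$layout
  out <- list(a = exp(theta[L$ta]),
              B = matrix(exp(theta[L$tb]), ctx$K, ctx$q),
              pi1 = stats::plogis(theta[L$lambda]))
  if (ctx$variant == "full") {
    out$g1 <- matrix(theta[L$g1], ctx$K, ctx$q)
    out$g_neg1 <- matrix(theta[L$g2], ctx$K, ctx$q)
    out$delta <- gumbel_softmax_delta(out$pi1, out$g1, out$g_neg1, ctx$spec$tau)
  } else {
    out$Gamma <- ctx$Gamma
  }
  if (ctx$spec$infer_sigma2) out$sigma2 <- exp(theta[L$ts])
  out
}
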