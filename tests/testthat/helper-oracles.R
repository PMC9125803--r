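# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: plain solve()/
# determinant() for the MVN, explicit edge-path enumeration for the tree
# covariance, textbook formulas for the diagnostics.

# MVN log-density via solve() and determinant() (no Cholesky caching).
oracle_mvn_logpdf <- function(y, mu, V) {
  k <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (k * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
}

# N(mean, sd^2) truncated to (0, Inf), with its normaliser.
oracle_truncnorm_logpdf <- function(x, mean, sd) {
  if (x <= 0) return(-Inf)
  dnorm(x, mean, sd, log = TRUE) - pnorm(mean / sd, log.p = TRUE)
}

oracle_gumbel_logpdf <- function(g) -g - exp(-g)

# Term-by-term joint log density of the full model, coded independently.
oracle_log_joint_full <- function(params, Y, X, V, spec) {
  K <- ncol(Y); q <- ncol(X)
  delta <- plogis((log(params$pi1) - log(1 - params$pi1) +
                     params$g1 - params$g_neg1) / spec$tau)
  M <- (2 * delta - 1) * params$B
  lp <- 0
  for (i in seq_len(nrow(Y)))
    lp <- lp + oracle_mvn_logpdf(Y[i, ], drop(M %*% X[i, ]), V)
  for (s in seq_len(K)) for (j in seq_len(q))
    lp <- lp + oracle_truncnorm_logpdf(params$B[s, j], params$a[j],
                                       sqrt(spec$sigma2))
  for (j in seq_len(q))
    lp <- lp + oracle_truncnorm_logpdf(params$a[j], 0, 1)
  lp <- lp + dbeta(params$pi1, spec$pi1_alpha, spec$pi1_beta, log = TRUE)
  lp + sum(oracle_gumbel_logpdf(params$g1)) +
    sum(oracle_gumbel_logpdf(params$g_neg1))
}

# Brute-force Brownian covariance: enumerate each tip's root-to-tip edge
# set by walking the edge matrix, then sum the lengths of shared edges.
oracle_brownian <- function(tree, taxa) {
  edges <- tree$edge
  lens <- tree$edge.length
  root <- setdiff(edges[, 1], edges[, 2])
  path_edges <- function(tip_label) {
    node <- match(tip_label, tree$tip.label)
    path <- integer(0)
    while (node != root) {
      e <- which(edges[, 2] == node)
      path <- c(path, e)
      node <- edges[e, 1]
    }
    path
  }
  paths <- lapply(taxa, path_edges)
  S <- length(taxa)
  V <- matrix(0, S, S, dimnames = list(taxa, taxa))
  for (i in seq_len(S)) for (j in seq_len(S))
    V[i, j] <- sum(lens[intersect(paths[[i]], paths[[j]])])
  V
}

# Split R-hat by its standard formula, written out longhand.
oracle_split_rhat <- function(x) {
  n <- nrow(x); half <- floor(n / 2)
  xs <- cbind(x[1:half, , drop = FALSE], x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  chain_means <- colMeans(xs)
  B <- nn / (m - 1) * sum((chain_means - mean(chain_means))^2)
  W <- mean(apply(xs, 2, var))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
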