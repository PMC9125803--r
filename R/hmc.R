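## Hamiltonian Monte Carlo engine.
##
## Plain (static-trajectory) HMC with:
##  * dual-averaging step-size adaptation towards a target acceptance rate,
##  * a diagonal mass matrix estimated from a mid-warmup window,
##  * trajectory-length jitter (uniform over {1, ..., L}) to break periodic
##    resonance,
##  * divergence detection (energy error > 1000 or a non-finite state).
## The sampler is deterministic given the R RNG state set by the caller.

.leapfrog <- function(theta, p, eps, n_steps, lpg, minv) {
  st <- lpg(theta)
  for (l in seq_len(n_steps)) {
    p <- p + 0.5 * eps * st$grad
    theta <- theta + eps * minv * p
    st <- lpg(theta)
    if (!is.finite(st$lp)) return(list(theta = theta, p = p, lp = -Inf))
    p <- p + 0.5 * eps * st$grad
  }
  list(theta = theta, p = p, lp = st$lp)
}

## Stan-style heuristic: double/halve eps until the one-step acceptance
## probability crosses 1/2.
.find_reasonable_eps <- function(theta, lpg, minv) {
  eps <- 0.1
  lp0 <- lpg(theta)$lp
  p <- stats::rnorm(length(theta)) / sqrt(minv)
  h0 <- lp0 - 0.5 * sum(p^2 * minv)
  step <- .leapfrog(theta, p, eps, 1L, lpg, minv)
  h1 <- step$lp - 0.5 * sum(step$p^2 * minv)
  ratio <- h1 - h0
  if (!is.finite(ratio)) ratio <- -Inf
  dir <- if (ratio > log(0.5)) 1 else -1
  for (i in 1:40) {
    eps <- eps * 2^dir
    step <- .leapfrog(theta, p, eps, 1L, lpg, minv)
    h1 <- step$lp - 0.5 * sum(step$p^2 * minv)
    ratio <- h1 - h0
    if (!is.finite(ratio)) ratio <- -Inf
    if ((dir == 1 && ratio <= log(0.5)) || (dir == -1 && ratio >= log(0.5)))
      break
  }
  max(eps, 1e-8)
}

## Run one chain. Returns post-warmup draws plus adaptation diagnostics.
.hmc_chain <- function(lpg, theta0, iterations, warmup, target_accept,
                       max_leapfrog, traj_length) {
  d <- length(theta0)
  theta <- theta0
  minv <- rep(1, d)                        # inverse mass (diagonal)
  n_keep <- iterations - warmup
  draws <- matrix(NA_real_, n_keep, d)
  accept <- numeric(iterations)
  divergent <- logical(n_keep)

  ## dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- .find_reasonable_eps(theta, lpg, minv)
  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75; da_iter <- 0L

  ## mass-estimation window inside warmup
  w_lo <- max(2L, floor(warmup * 0.25)); w_hi <- floor(warmup * 0.75)
  win <- matrix(NA_real_, max(w_hi - w_lo + 1L, 1L), d); w_n <- 0L

  for (it in seq_len(iterations)) {
    p0 <- stats::rnorm(d) / sqrt(minv)
    st0 <- lpg(theta)
    h0 <- st0$lp - 0.5 * sum(p0^2 * minv)
    L_base <- min(max_leapfrog, max(1L, as.integer(round(traj_length / eps))))
    ## jitter in [L/2, L] breaks periodic resonance without wasting most
    ## trajectories on very short paths
    L_lo <- max(1L, L_base %/% 2L)
    n_steps <- if (L_lo >= L_base) L_base
               else L_lo + sample.int(L_base - L_lo + 1L, 1L) - 1L
    prop <- .leapfrog(theta, p0, eps, n_steps, lpg, minv)
    h1 <- prop$lp - 0.5 * sum(prop$p^2 * minv)
    dH <- h1 - h0
    div <- !is.finite(dH) || dH < -1000
    alpha <- if (is.finite(dH)) min(1, exp(dH)) else 0
    if (!div && stats::runif(1) < alpha) theta <- prop$theta
    accept[it] <- alpha

    if (it <= warmup) {
      da_iter <- da_iter + 1L
      h_bar <- (1 - 1 / (da_iter + t0)) * h_bar +
        (target_accept - alpha) / (da_iter + t0)
      log_eps <- mu - sqrt(da_iter) / gamma_da * h_bar
      wt <- da_iter^(-kappa)
      log_eps_bar <- wt * log_eps + (1 - wt) * log_eps_bar
      eps <- exp(log_eps)
      if (it >= w_lo && it <= w_hi) { w_n <- w_n + 1L; win[w_n, ] <- theta }
      if (it == w_hi && w_n >= 10L) {
        v <- apply(win[seq_len(w_n), , drop = FALSE], 2L, stats::var)
        minv <- (w_n / (w_n + 5)) * v + 1e-3 * (5 / (w_n + 5))
        minv[minv < 1e-8] <- 1e-8
        ## re-initialise step-size search for the new metric
        eps <- .find_reasonable_eps(theta, lpg, minv)
        mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; da_iter <- 0L
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      k <- it - warmup
      draws[k, ] <- theta
      divergent[k] <- div
    }
  }
  list(draws = draws, eps = eps, accept_rate = mean(accept[-seq_len(warmup)]),
       divergent = divergent)
}
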