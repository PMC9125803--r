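#' Simulation configuration
#'
#' The stated benchmark world: n = 100 samples, S = 10 species, an intercept
#' plus p = 2 standard-normal covariates with true global effects
#' (1, 0.5, 0), magnitude noise sigma2 = 0.1, and multinomial counts with
#' 100 * S trials per sample. A random Brownian-motion tree supplies the
#' species covariance (identity when `use_tree = FALSE`).
#'
#' @param n number of samples, >= 2.
#' @param S number of species, >= 2.
#' @param p number of non-intercept covariates (an intercept column of ones
#'   is always included as column 1 of the design).
#' @param a length-(p + 1) vector of true nonnegative global effects, the
#'   first entry belonging to the intercept.
#' @param sigma2 variance of the truncated-Gaussian magnitude draws.
#' @param trials_multiplier multinomial trials per sample = multiplier * S.
#' @param seed integer seed controlling the whole generation chain.
#' @param scale_c covariance scale c.
#' @param use_tree if `FALSE`, skip the tree and use the identity covariance.
#' @param per_species_sigma2 optional length-(S - 1) vector of heterogeneous
#'   magnitude variances (sensitivity analyses); overrides `sigma2` per row.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n = 100L, S = 10L, p = 2L, a = c(1, 0.5, 0),
                              sigma2 = 0.1, trials_multiplier = 100L,
                              seed = 1L, scale_c = 1, use_tree = TRUE,
                              per_species_sigma2 = NULL) {
  n <- as.integer(n); S <- as.integer(S); p <- as.integer(p)
  .assert(n >= 2L, "n must be >= 2")
  .assert(S >= 2L, "S must be >= 2")
  .assert(p >= 0L, "p must be >= 0")
  .assert(length(a) == p + 1L, "a must have length p + 1 (intercept first)")
  .assert(all(a >= 0), "global effects must be nonnegative")
  .assert(sigma2 > 0, "sigma2 must be > 0")
  .assert(trials_multiplier >= 1L, "trials_multiplier must be >= 1")
  if (!is.null(per_species_sigma2))
    .assert(length(per_species_sigma2) == S - 1L && all(per_species_sigma2 > 0),
            "per_species_sigma2 must be S - 1 positive values")
  structure(list(n = n, S = S, p = p, a = a, sigma2 = sigma2,
                 trials_multiplier = as.integer(trials_multiplier),
                 seed = as.integer(seed), scale_c = scale_c,
                 use_tree = use_tree,
                 per_species_sigma2 = per_species_sigma2),
            class = "simulation_config")
}

#' Simulate a random phylogenetic tree
#'
#' Random rooted binary tree with `S` labeled tips (`t1` ... `tS`) and
#' Uniform(0, 1) branch lengths, via `ape::rtree`.
#'
#' @param S number of tips, >= 2.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return an `ape::phylo` tree.
#' @export
simulate_tree <- function(S, seed = NULL) {
  .assert(S >= 2L, "a tree needs at least 2 tips (S >= 2)")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(S)
  .validate_tree(tree)
  tree
}

#' Simulate a benchmark dataset with full ground truth
#'
#' Runs the complete generative chain: random tree, Brownian species
#' covariance c Sigma (reference taxon dropped), standard-normal covariates
#' with an intercept, Bernoulli(0.5) signs mapped to \{-1, +1\},
#' truncated-Gaussian magnitudes beta_(s,j) ~ N+(a_j, sigma2) (exact
#' inverse-CDF draws), MVN log-ratios y_i ~ MVN((Gamma (*) B) x_i, c Sigma),
#' proportions by the inverse log-ratio map, and multinomial counts with
#' `trials_multiplier * S` trials. Every intermediate is retained.
#'
#' @param cfg a [simulation_config].
#' @return object of class `simulation_truth` with fields `tree`, `cov`
#'   (`species_covariance`), `X` (`design_matrix`), `Gamma`, `B`, `a`, `y`
#'   (`log_ratio_table`), `proportions`, `counts` (`count_table`), `config`.
#' @export
simulate_dataset <- function(cfg) {
  .assert(inherits(cfg, "simulation_config"), "cfg must be a simulation_config")
  set.seed(cfg$seed)
  S <- cfg$S; n <- cfg$n; p <- cfg$p
  K <- S - 1L; q <- p + 1L
  taxa <- paste0("t", seq_len(S))
  reference <- taxa[S]

  tree <- NULL
  if (cfg$use_tree) {
    tree <- simulate_tree(S)
    Vfull <- brownian_covariance(tree, taxa)
    cov <- model_covariance(Vfull, reference, cfg$scale_c)
  } else {
    cov <- model_covariance(NULL, scale_c = cfg$scale_c,
                            taxon_ids = taxa[seq_len(K)])
  }

  samples <- sprintf("s%03d", seq_len(n))
  Xraw <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(samples, if (p > 0) paste0("x", seq_len(p))))
  X <- design_matrix(Xraw, sample_ids = samples, add_intercept = TRUE)

  Gamma <- matrix(sample(c(-1, 1), K * q, replace = TRUE), K, q)
  sdmat <- if (is.null(cfg$per_species_sigma2)) {
    matrix(sqrt(cfg$sigma2), K, q)
  } else matrix(sqrt(cfg$per_species_sigma2), K, q)
  B <- matrix(.rtruncnorm_pos(K * q,
                              mean = rep(cfg$a, each = K),
                              sd = as.vector(sdmat)), K, q)
  dimnames(Gamma) <- dimnames(B) <- list(taxa[seq_len(K)], X$covariate_names)

  Mu <- linear_predictor(Gamma, B, X$values)
  U <- chol(cov$values + diag(1e-8 * mean(diag(cov$values)), K))
  Yv <- Mu + matrix(stats::rnorm(n * K), n, K) %*% U
  y <- log_ratio_table(Yv, samples, taxa[seq_len(K)], reference)

  rho <- inverse_log_ratio(y)
  trials <- cfg$trials_multiplier * S
  Z <- t(apply(rho$values, 1L, function(pr) stats::rmultinom(1L, trials, pr)))
  counts <- count_table(Z, samples, taxa)

  structure(list(tree = tree, cov = cov, X = X, Gamma = Gamma, B = B,
                 a = cfg$a, y = y, proportions = rho, counts = counts,
                 config = cfg),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: n = %d, S = %d, p = %d (+ intercept), seed = %d\n",
    x$config$n, x$config$S, x$config$p, x$config$seed))
  cat("  true global effects:", paste(x$a, collapse = ", "), "\n")
  invisible(x)
}

#' Replicate a recovery experiment
#'
#' Generates `n_replicates` independent datasets (replicate k reseeds the
#' generator at `cfg$seed + k`) and optionally fits the requested model
#' variants to each, tabulating posterior-mean estimates of the global
#' effects and magnitudes against the simulation truth — the layout of the
#' benchmark recovery experiment. Fit failures are recorded per replicate
#' rather than aborting the study.
#'
#' @param cfg a [simulation_config].
#' @param n_replicates number of independent datasets.
#' @param variants subset of `c("full", "conditional", "oracle")`; `NULL`
#'   generates data only.
#' @param spec a [model_spec] used for fitting.
#' @param sc a [sampler_config]; replicate k uses sampler seed
#'   `sc$seed + 100 * k`.
#' @param response `"exact"` fits the simulated log-ratios directly (the
#'   recovery experiment proper); `"counts"` re-derives them from the
#'   multinomial counts through the pseudocount pipeline, adding the
#'   count-resampling noise an end-to-end analysis would see.
#' @param keep_fits retain the full `posterior_samples` objects (memory
#'   heavy); the summary table is always built.
#' @return object of class `replicate_study`: `truths` (list), `fits`
#'   (list of lists or NULL), `summary` (data frame with one row per
#'   (replicate, variant, parameter): truth and posterior-mean estimate),
#'   `errors` (per-replicate messages).
#' @export
replicate_study <- function(cfg, n_replicates, variants = "full",
                            spec = model_spec(sigma2 = cfg$sigma2,
                                              scale_c = cfg$scale_c),
                            sc = sampler_config(), response = c("exact", "counts"),
                            keep_fits = FALSE) {
  response <- match.arg(response)
  .assert(n_replicates >= 1L, "need at least one replicate")
  if (!is.null(variants))
    .assert(all(variants %in% c("full", "conditional", "oracle")),
            "unknown variant")
  truths <- vector("list", n_replicates)
  fits <- if (keep_fits) vector("list", n_replicates)
  rows <- list()
  errors <- list()
  for (k in seq_len(n_replicates)) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k
    truth <- simulate_dataset(cfg_k)
    truths[[k]] <- truth
    yk <- if (response == "exact") truth$y else
      log_ratio_transform(counts_to_proportions(truth$counts, 0.5),
                          truth$y$reference_taxon)
    if (keep_fits) fits[[k]] <- list()
    for (v in variants %||% character()) {
      sck <- sc; sck$seed <- sc$seed + 100L * k
      fit <- tryCatch(
        switch(v,
          full = fit_full(yk, truth$X, truth$cov, spec, sck),
          conditional = fit_conditional(
            yk, truth$X, truth$cov, spec, sck,
            signs = estimate_signs(yk, truth$X)),
          oracle = fit_conditional(yk, truth$X, truth$cov, spec, sck,
                                   signs = truth$Gamma,
                                   variant_tag = "oracle")),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[length(errors) + 1L]] <-
          sprintf("replicate %d, %s: %s", k, v, conditionMessage(fit))
        next
      }
      if (keep_fits) fits[[k]][[v]] <- fit
      rows[[length(rows) + 1L]] <- .truth_vs_estimate(truth, fit, k, v)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows)
  structure(list(truths = truths, fits = fits, summary = summary,
                 errors = unlist(errors)),
            class = "replicate_study")
}

.truth_vs_estimate <- function(truth, fit, replicate, variant) {
  q <- fit$q; K <- fit$K
  pm <- apply(fit$draws, 3L, mean)
  a_par <- sprintf("a[%d]", seq_len(q))
  b_par <- as.vector(outer(seq_len(K), seq_len(q),
                           function(s, j) sprintf("beta[%d,%d]", s, j)))
  data.frame(
    replicate = replicate, variant = variant,
    parameter = c(a_par, b_par),
    covariate = c(fit$covariate_names,
                  rep(fit$covariate_names, each = K)),
    truth = c(truth$a, as.vector(truth$B)),
    estimate = unname(pm[c(a_par, b_par)]))
}

#' Write one simulated replicate to disk
#'
#' Plain-text layout: `counts.tsv`, `covariates.tsv` (non-intercept columns),
#' `tree.nwk` (when a tree was used) and `truth.json` holding a, B, Gamma,
#' sigma2 and the seed.
#'
#' @param truth a `simulation_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_replicate <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(truth$counts, file.path(dir, "counts.tsv"))
  Xn <- truth$X$values[, !truth$X$intercept, drop = FALSE]
  .write_labeled_matrix(Xn, file.path(dir, "covariates.tsv"), "sample")
  if (!is.null(truth$tree))
    ape::write.tree(truth$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(a = truth$a, B = truth$B, Gamma = truth$Gamma,
         sigma2 = truth$config$sigma2, seed = truth$config$seed,
         reference_taxon = truth$y$reference_taxon),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(dir)
}
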