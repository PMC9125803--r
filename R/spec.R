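#' Design matrix
#'
#' Covariate matrix for the regression, one row per sample. An intercept
#' column of ones may be added with `add_intercept`; constant-zero columns
#' are rejected because they carry no information yet would still receive a
#' global-effect parameter.
#'
#' @param values n x p numeric matrix of covariates.
#' @param covariate_names p column labels.
#' @param sample_ids optional n row labels.
#' @param add_intercept prepend a column of ones named `"intercept"`.
#' @return object of class `design_matrix` with fields `values`,
#'   `covariate_names`, `sample_ids`, `intercept` (logical per column).
#' @export
design_matrix <- function(values, covariate_names = colnames(values),
                          sample_ids = rownames(values),
                          add_intercept = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .assert(all(is.finite(values)), "covariates must be finite")
  covariate_names <- as.character(
    covariate_names %||% paste0("x", seq_len(ncol(values))))
  intercept <- apply(values, 2L, function(v) all(v == 1))
  if (add_intercept) {
    values <- cbind(1, values)
    covariate_names <- c("intercept", covariate_names)
    intercept <- c(TRUE, intercept)
  }
  .assert(!any(apply(values, 2L, function(v) all(v == 0))),
          "constant-zero covariate column")
  .unique_labels(covariate_names, "covariate")
  sample_ids <- as.character(sample_ids %||% paste0("sample", seq_len(nrow(values))))
  dimnames(values) <- list(sample_ids, covariate_names)
  structure(list(values = values, covariate_names = covariate_names,
                 sample_ids = sample_ids, intercept = intercept),
            class = "design_matrix")
}

#' Model specification
#'
#' Collects every prior hyperparameter and structural constant of the
#' hierarchical log-ratio model:
#' * global effects a_j have truncated-Gaussian N+(0, 1) priors;
#' * species magnitudes beta_(s,j) ~ N+(a_j, sigma2), strictly positive;
#' * signs gamma_(s,j) = 2 delta_(s,j) - 1 with delta from a Gumbel-Softmax
#'   relaxation at temperature `tau` (small tau = near-binary signs);
#' * the positive-sign probability pi1 has a Beta(`pi1_alpha`, `pi1_beta`)
#'   prior (flat by default);
#' * `sigma2` is a single scalar shared across species and covariates, fixed
#'   at 0.1 by default, or inferred under a half-Gaussian(0, 1) hyperprior
#'   when `sigma2 = "infer"`.
#'
#' @param sigma2 positive scalar, or the string `"infer"`.
#' @param tau Gumbel-Softmax temperature, > 0. Default 0.1: small enough that
#'   relaxed signs are near-binary, large enough for usable gradients.
#' @param pi1_alpha,pi1_beta Beta hyperparameters for pi1, both > 0.
#' @param scale_c covariance scale c > 0.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(sigma2 = 0.1, tau = 0.1, pi1_alpha = 1, pi1_beta = 1,
                       scale_c = 1) {
  infer_sigma2 <- identical(sigma2, "infer")
  if (!infer_sigma2) {
    .assert(is.numeric(sigma2) && length(sigma2) == 1L && sigma2 > 0,
            "sigma2 must be a positive scalar or \"infer\"")
  }
  .assert(is.numeric(tau) && length(tau) == 1L && tau > 0, "tau must be > 0")
  .assert(pi1_alpha > 0 && pi1_beta > 0, "Beta hyperparameters must be > 0")
  .assert(is.numeric(scale_c) && length(scale_c) == 1L && scale_c > 0,
          "scale_c must be > 0")
  structure(list(sigma2 = if (infer_sigma2) NA_real_ else sigma2,
                 infer_sigma2 = infer_sigma2, tau = tau,
                 pi1_alpha = pi1_alpha, pi1_beta = pi1_beta,
                 scale_c = scale_c),
            class = "model_spec")
}

#' @rdname model_spec
#' @param spec a `model_spec`.
#' @param path file to write a flat `key = value` configuration to.
#' @export
write_model_spec <- function(spec, path) {
  keys <- list(sigma2 = if (spec$infer_sigma2) "infer" else spec$sigma2,
               tau = spec$tau, pi1_alpha = spec$pi1_alpha,
               pi1_beta = spec$pi1_beta, scale_c = spec$scale_c)
  writeLines(sprintf("%s = %s", names(keys), unlist(keys)), path)
}

#' @rdname model_spec
#' @export
read_model_spec <- function(path) {
  kv <- .read_kv(path)
  .check_keys(kv, c("sigma2", "tau", "pi1_alpha", "pi1_beta", "scale_c"))
  num <- function(k) as.numeric(kv[[k]])
  model_spec(sigma2 = if (identical(kv$sigma2, "infer")) "infer" else num("sigma2"),
             tau = num("tau"), pi1_alpha = num("pi1_alpha"),
             pi1_beta = num("pi1_beta"), scale_c = num("scale_c"))
}

#' Sampler configuration
#'
#' Settings for the Hamiltonian Monte Carlo runs. `iterations` is the total
#' per chain, the first `warmup_fraction` of which is used for step-size and
#' mass-matrix adaptation and discarded. The benchmark default (4 chains x
#' 8000 iterations) mirrors the headline simulation runs; tests use smaller
#' desk-scale profiles.
#'
#' @param chains number of chains, >= 1 (>= 2 needed for split R-hat).
#' @param iterations total HMC iterations per chain.
#' @param warmup_fraction fraction of iterations used as warmup, in (0, 1).
#' @param seed integer seed; chain k uses `seed + k - 1`.
#' @param target_accept dual-averaging target acceptance probability.
#' @param rhat_threshold convergence flag threshold for split R-hat.
#' @param max_leapfrog cap on leapfrog steps per trajectory.
#' @param traj_length nominal integration time; steps ~= traj_length / stepsize.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iterations = 8000L,
                           warmup_fraction = 0.5, seed = 1L,
                           target_accept = 0.8, rhat_threshold = 1.01,
                           max_leapfrog = 128L, traj_length = 2) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  .assert(chains >= 1L, "need at least one chain")
  .assert(iterations >= 4L, "too few iterations")
  .assert(warmup_fraction > 0 && warmup_fraction < 1,
          "warmup_fraction must be in (0, 1)")
  warmup <- as.integer(floor(iterations * warmup_fraction))
  .assert(iterations > warmup, "iterations must exceed warmup")
  .assert(target_accept > 0 && target_accept < 1, "target_accept in (0, 1)")
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 warmup_fraction = warmup_fraction, seed = as.integer(seed),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold,
                 max_leapfrog = as.integer(max_leapfrog),
                 traj_length = traj_length),
            class = "sampler_config")
}

.read_kv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  .assert(all(grepl("=", lines)), "config lines must be 'key = value'")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}

.check_keys <- function(kv, required, optional = character()) {
  missing <- setdiff(required, names(kv))
  .assert(length(missing) == 0L, "missing required config key(s): %s",
          paste(missing, collapse = ", "))
  extra <- setdiff(names(kv), c(required, optional))
  .assert(length(extra) == 0L, "unknown config key(s): %s",
          paste(extra, collapse = ", "))
  invisible(kv)
}
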