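# hblr — hierarchical Bayesian log-ratio regression for microbiome associations

`hblr` detects associations between sample covariates and microbial
composition at two levels simultaneously: a **global effect** `a_j`
summarising how strongly covariate *j* moves the community as a whole, and
**taxon-specific signed effects** `γ_{s,j} β_{s,j}` saying which taxa move
and in which direction. It is aimed at microbiome studies (16S or shotgun
count tables) where distance-based tests (PERMANOVA, ANOSIM, kernel tests)
would give a p-value but no effect size, and per-taxon regressions would
give no community-level answer.

## Model

Counts are compositional: with proportions `ρ_i` estimated from counts
(pseudocount for zeros) and a reference taxon *S*, the log-ratios
`y_{i,s} = log(ρ_{i,s}/ρ_{i,S})` are modelled as

    y_i ~ MVN( (Γ ⊙ B) x_i , c Σ )
    β_{s,j} ~ N+(a_j, σ²)        γ_{s,j} = 2 δ_{s,j} − 1
    a_j ~ N+(0, 1)               π₁ ~ Beta(1, 1)

where `B > 0` are effect magnitudes, `Γ ∈ {−1,+1}` signs with a
Gumbel-Softmax relaxation `δ` (temperature `τ`) so the posterior is
differentiable end-to-end, and `Σ` is the Brownian-motion phylogenetic
covariance read off a rooted tree (shared root-to-MRCA branch length;
identity if no tree). Inference is Hamiltonian Monte Carlo with analytic
gradients, implemented in the package (no Stan dependency). A cheaper
**conditional** variant fixes the signs from per-taxon least squares and
samples the rest. See `vignettes/hblr-methods.Rmd` for the full account.

## Worked example

Simulate a benchmark dataset (n = 100 samples, S = 10 taxa, intercept plus
two covariates with true global effects 1, 0.5 and 0) and fit the full
model:

```r
library(hblr)
cfg   <- simulation_config(seed = 1)        # n = 100, S = 10, a = (1, 0.5, 0)
truth <- simulate_dataset(cfg)
fit   <- fit_full(truth$y, truth$X, truth$cov,
                  spec = model_spec(sigma2 = 0.1),
                  sc = sampler_config(chains = 2, iterations = 2000, seed = 1))
global_effects_summary(fit)
```

which prints (about 15 s):

```
  covariate  mean    sd    q2.5 q97.5 rhat ess
1 intercept 1.095 0.129 0.84155 1.349 1.00 237
2        x1 0.535 0.132 0.27751 0.799 1.01 420
3        x2 0.173 0.116 0.00842 0.443 1.01 573
```

The posterior means recover the simulated global effects (1, 0.5, 0): the
intercept and `x1` credible intervals sit on their true values, and `x2`
(simulated at zero) is small but positively biased — expected, because the
global effect is the prior mean of strictly positive magnitudes, so the
half-normal spread of near-zero effects leaves a floor of about 0.2.
`signed_effects(fit)` gives the taxon-by-covariate matrix of posterior
mean `γ·β` (first rows shown):

```
   intercept    x1    x2
t1      1.03 -0.52  0.16
t2      0.82  0.37  0.46
t3      1.46 -0.33 -0.62
t4      1.12 -0.40 -0.27
```

Longer chains (the benchmark profile is 4 × 8000) tighten taxon-level
magnitude calibration; 2 × 2000 is adequate for the global effects.

## Command line

```sh
Rscript inst/cli/hblr simulate --config sim.cfg --out sims/
Rscript inst/cli/hblr fit --counts counts.tsv --covariates covs.tsv \
    --tree tree.nwk --variant full --chains 4 --iterations 8000 \
    --seed 1 --out results/
Rscript inst/cli/hblr report --posterior results/posterior.tsv \
    --top-k 10 --out report/
```

`fit` accepts TSV/CSV counts (samples × taxa, first column sample labels)
and covariates, an optional newick tree, and flags `--reference-taxon`,
`--pseudocount`, `--tau`, `--scale-c`, `--sigma2` (a number or `infer`),
`--variant full|conditional`. Outputs are plain TSV — `posterior.tsv`
(chain, iteration, parameter, value), `summary.tsv` (mean, sd, 2.5%,
97.5%, R-hat, ESS per parameter), `diagnostics.txt` — plus a
`manifest.json` holding every setting needed to re-execute the run
bit-identically. `report` writes a per-covariate posterior density grid
(`global_density.tsv`) and the ranked signed taxon-effect matrix
(`species_effects.tsv`).

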