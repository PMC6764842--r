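# blockprs

Block-wise Bayesian polygenic risk scores from GWAS summary statistics.

## What problem this solves

GWAS and meta-GWAS consortia publish, per variant, the effect estimate of a
*univariate* regression of the trait on that variant. A polygenic risk
score (PRS) built directly from these marginal effects over-represents
every signal tagged by several correlated variants, because linkage
disequilibrium (LD) is ignored. `blockprs` infers *multivariate*,
LD-adjusted weights from the summary statistics alone, using a reference
genotype panel only to estimate the LD structure, and is aimed at
statistical geneticists building genome-wide risk predictors when
individual-level training data cannot be shared.

## The method

For mean-centred trait and dosages, the multivariate model
`y ~ N(Xβ, σ²I)` is re-expressed through quantities recoverable from
summaries:

```
X'y ~ MVN(X'Xβ, X'X σ²),      X'X = L'L  (Cholesky)
L'⁻¹X'y ~ MVN(Lβ, σ²I)
```

with `x_p'y` rebuilt from the univariate effect, allele frequency and
sample size (`β̂_p · n · 2f_p(1−f_p)`), and `X'X` plugged in from the
reference panel. Inference runs in two steps:

1. **Step 1 (local LD)** — variants are split into blocks of 100 within
   chromosomes. Each block gets a sparse Bayesian regression sampled by
   reversible-jump MCMC: a latent selection vector with a
   `Beta(1, λP)`-binomial prior (prior odds of any given variant
   `1/(λP)`), Gaussian effects with `σβ ~ Unif(0.05, 2)`, and
   `σ² ~ InvGamma(0.01, 0.01)`. Weights are model-averaged posterior
   means, so sparsity and local heritability adapt per block. Blocks are
   independent and run in parallel, bit-reproducibly for any worker count.
2. **Step 2 (long-range LD)** — per-block scores
   `s_ib = Σ_p x_ibp β̂_bp` become covariates of a second summary-level
   regression, `S'y ~ MVN(S'Sδ, S'Sσ²)`; the MLE `δ̂` rescales each
   block, removing double counting of signals that leak across blocks
   (e.g. MHC-scale LD). Genome-wide weights are `β̂G = (δ̂₁β̂₁, …, δ̂_Bβ̂_B)`.

The sparsity parameter λ is tuned over `{0.001, 0.01, 0.1, 1}` by
validation AUC (binary) or r² (continuous). Baselines (clumping +
p-value thresholding), PLINK `.bed/.bim/.fam` I/O, harmonization/QC, and
a synthetic-data generator with block and cross-block LD are included, so
the whole pipeline is testable offline.

## Worked example

```r
library(blockprs)

# simulate a small study: 200 variants in 4 LD blocks, two equal causal
# effects per block, h2 = 0.4
cfg <- sim_config(P = 200, block_size = 50, n_train = 2000, n_ref = 1000,
                  n_test = 1000, n_causal = 8, h2 = 0.4, seed = 42)
sims <- simulate_genotypes(cfg)
causal <- c(10, 35, 60, 85, 110, 135, 160, 185)
braw <- numeric(200)
braw[causal] <- rep(c(1, -1), 4) / apply(sims$train$genotypes[, causal], 2, sd)
gc <- scale(sims$train$genotypes[, causal], center = TRUE, scale = FALSE)
beta_true <- braw * sqrt(cfg$h2) / sd(as.vector(gc %*% braw[causal]))
trait <- simulate_trait(sims$train, cfg, beta_true = beta_true)

# a "GWAS": univariate summaries on the training panel
stats <- compute_univariate_summaries(sims$train, trait$y)

# two-step fit against the reference panel
h <- harmonize(stats, sims$ref)
fit <- fit_two_step(h$stats, h$panel,
                    sampler_config(n_iter = 10000, seed = 7,
                                   prior = prior_config(lambda = 0.1)),
                    block_size = 50)
print(fit)
#> two_step_fit: 200 variants in 4 blocks
#>   lambda: 0.1
#>   posterior mean model size per block: 2.25, 2.46, 2.29, 2.52
#>   delta range: [ 1.009 , 1.083 ]

# score held-out individuals and evaluate
test_y <- simulate_trait(sims$test, cfg, beta_true = beta_true)$y
prs <- score_individuals(sims$test, fit$weights)
evaluate_prs(prs, test_y)$r2
#> [1] 0.3577936
```

Reading the output: each block's posterior mean model size sits near the
true two causal variants per block (the sampler adapts sparsity per
block); `delta` near 1 says the blocks carry no shared long-range LD, so
Step 2 changes little here; and the held-out r² of 0.36 approaches the
simulated heritability of 0.4, the ceiling for any predictor on these
data. The top-PIP variants (`fit$weights$pip`) are exactly the eight
simulated causal ones.

A command-line wrapper with `simulate` / `train` / `score` subcommands is
installed at `inst/cli/blockprs.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/blockprs.R", package="blockprs"))')" \
    simulate --out sim --p 500 --seed 42
```

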