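---
title: "Methods: block-wise Bayesian polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-wise Bayesian polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide association studies share, for each of hundreds of thousands of
variants, the *univariate* effect estimate of a one-at-a-time regression of
the trait on that variant, together with its standard error, allele
frequency, and sample size. Polygenic risk scores built directly from these
marginal effects double count every signal that is tagged by several
correlated variants, because linkage disequilibrium (LD) is ignored.
`blockprs` recovers *multivariate*, LD-adjusted weights from the univariate
summaries, using only a modest reference panel of genotypes to estimate the
LD structure, and does so in two steps so that the expensive model search
runs independently — and therefore in parallel — on small blocks of
variants.

## The model

For a mean-centred trait $y$ and mean-centred dosage matrix $X$ of $P$
variants on $n$ individuals, the target is the multivariate linear model

$$y \sim N(X\beta,\; \sigma^2 I).$$

Multiplying through by $X'$ gives a model for quantities that *are*
recoverable from summary data:

$$X'y \sim \mathrm{MVN}(X'X\beta,\; X'X\sigma^2).$$

* $X'y$ is reconstructed per variant from the univariate effect
  $\hat\beta_p$, the effect-allele frequency $f_p$, and $n$:
  $x_p'y = \hat\beta_p \, n \, 2f_p(1-f_p)$. This is the exact OLS identity
  $\hat\beta_p = x_p'y / x_p'x_p$ with the Hardy–Weinberg genotype variance
  $2f(1-f)$ standing in for $x_p'x_p/n$, the only variance estimate the
  summary data offer. The substitution carries a relative error of order
  $1/\sqrt{n}$ (the sampling error of the HWE variance), which the test
  suite measures directly; plugging in the in-sample variance instead makes
  the identity exact to round-off.
* $X'X$ is the *plug-in* cross-product of mean-centred reference-panel
  dosages, rescaled by $n_\mathrm{gwas}/n_\mathrm{ref}$ so the likelihood
  carries the GWAS sample size. Covariance (not correlation) scale is used
  because the model above lives on the natural dosage scale.

An upper-triangular Cholesky factor $X'X = L'L$ whitens the model into an
ordinary regression with independent Gaussian errors,

$$z \equiv L'^{-1}X'y \sim \mathrm{MVN}(L\beta,\; \sigma^2 I),$$

which is what the sampler evaluates; each likelihood update touches a
single column of $L$ and costs $O(p)$.

For binary traits the univariate log odds ratios are first mapped to the
effects a linear regression of the standardized 0/1 outcome would have
produced, via their z-scores: $\hat\beta \approx z/\sqrt{n\,2f(1-f)}$ with
$z = \log\mathrm{OR}/\mathrm{SE}$. This is the standard device for using a
linear summary-statistic framework with case–control data; it is accurate
for the small per-variant effects typical of complex traits and is
validated in the tests against paired logistic/linear regressions on
simulated liability-threshold data (correlation > 0.99).

## Priors and sparsity

A latent inclusion vector $\gamma$ selects which variants have nonzero
effects. The proportion of nonzero effects $\pi$ carries a
$\mathrm{Beta}(1, \lambda P)$ prior, which we integrate out analytically,
leaving an exchangeable beta-binomial mass per configuration of size $k$:

$$\log P(\gamma) = \log B(k + 1,\; P - k + \lambda P) - \log B(1, \lambda P).$$

Marginally, the prior odds that a *given* variant is included are
$1/(\lambda P)$, while the odds of *any* effect in the block are $1/\lambda$
— the built-in multiplicity correction. Larger $\lambda$ means sparser
models. Because $\pi$ is random rather than fixed, each block calibrates
its own sparsity and effect scale; this is what lets signal-dense regions
(an MHC-like block) keep many variants while most blocks stay nearly
empty. $\lambda$ itself is tuned over the grid
$\{0.001, 0.01, 0.1, 1\}$ by validation performance (`select_lambda()`).

Selected effects have $\beta_\gamma \sim N(0, I\sigma_\beta^2)$ with
$\sigma_\beta \sim \mathrm{Unif}(0.05, 2)$ — vague on the scale of
standardized-trait effects — and the residual variance has the standard
vague prior $\sigma^2 \sim \mathrm{InvGamma}(0.01, 0.01)$. The trait is
assumed standardized (unit variance) so that $\sigma^2$ is comparable
across blocks; supply trait-SD-scaled effects otherwise.

## The reversible-jump sampler

Posterior inference uses reversible-jump MCMC over $(\gamma, \beta_\gamma,
\sigma_\beta, \sigma^2)$ with six moves (default probabilities in
parentheses): add a variant with its effect drawn from the
$N(0,\sigma_\beta^2)$ prior (0.2), delete a variant (0.2), swap an included
for an excluded variant (0.1), Gaussian random walk on one effect (0.3),
reflected random walk on $\sigma_\beta$ within its support (0.1), and a
conjugate inverse-gamma Gibbs draw of $\sigma^2$ (0.1). Drawing new effects
from their prior makes the effect-prior density cancel against the
proposal density, so no Jacobian bookkeeping is needed. At boundary states
(the null or saturated model) impossible moves are resampled among the
valid ones; the per-state renormalization enters the proposal ratio, so
detailed balance is exact — a property verified empirically by the
prior-recovery test (flat likelihood, $\chi^2$ goodness of fit of the
sampled model-size distribution against the beta-binomial prior).

Numerical and design details:

* **Initialization** — null model, $\sigma_\beta$ at the geometric mean of
  its support ($\approx 0.32$), $\sigma^2 = 1$; deterministic.
* **Adaptation** — the two random-walk step sizes adapt every 50 proposals
  *during burn-in only* (factor 1.25 toward a 0.25–0.45 acceptance band)
  and are frozen afterwards, preserving the stationary distribution.
* **Burn-in** — first 50% of iterations discarded; 200,000 iterations per
  block is the reference setting and takes seconds per 100-variant block.
* **Incremental likelihood** — residuals and their sum of squares are
  updated in $O(p)$ per move and recomputed from scratch every 20,000
  iterations to cancel round-off drift.
* **Model averaging** — the reported weight of a variant is its posterior
  mean effect including zeros from iterations that excluded it; the
  posterior inclusion probability (PIP) and the block's posterior mean
  model size ($\sum$ PIP) come from the same pass.
* **Oracle** — for blocks of $p \le 15$ with $\sigma_\beta, \sigma^2$
  fixed, `enumerate_posterior()` scores all $2^p$ selections with the
  conjugate marginal likelihood
  $z \sim \mathrm{MVN}(0, \sigma^2 I + \sigma_\beta^2 L_S L_S')$;
  the MCMC inclusion probabilities are required to match it within
  $\pm 0.03$ at 200,000 iterations.

## Two steps: local then long-range LD

**Step 1.** Variants are partitioned into contiguous blocks of 100 within
each chromosome (blocks never straddle chromosome boundaries — those are
free independence structure). Each block is fitted independently with its
own seed derived deterministically from (global seed, block index), so a
run is bitwise reproducible for any worker count. The full-rank requirement
on the plug-in $X'X$ caps the block size at (well below) the reference
panel size; rank-deficient blocks — e.g. duplicated variants that escaped
pruning — are refused with the block named, while merely ill-conditioned
ones get a single ridge jitter of $10^{-6}\,\overline{\mathrm{diag}}$.

**Step 2.** Appending the block weights ignores correlation *across*
blocks, which double counts any signal visible in several blocks
(long-range LD, MHC-style). Treating the per-block scores
$s_{ib} = \sum_p x_{ibp} \hat\beta_{bp}$ as $B$ covariates, a second
summary-level regression estimates scaling factors $\delta$:

$$S'y \sim \mathrm{MVN}(S'S\delta,\; S'S\sigma^2),$$

with $S'S$ the plug-in cross-product of centred reference block scores
(rescaled by $n_\mathrm{gwas}/n_\mathrm{ref}$) and $S'y$ built exactly as
$X'y$ was: marginal effect times sum of squares. By construction each
block score has marginal effect 1 on the trait — its weights are already
on the trait scale — so $S'y = \mathrm{diag}(S'S)$. $\hat\delta$ is the
MLE solving $S'S\delta = S'y$ ($\sigma^2$ profiles out); no model
selection is applied at this level, since sparsity was already imposed
within blocks. Genome-wide weights are $\hat\beta^G_{bp} = \hat\delta_b
\hat\beta_{bp}$.

Degenerate cases: a block whose weights are all zero has a zero-variance
score; its $\delta$ is fixed at 0 (keeping output alignment) rather than
dropped. Exactly collinear block scores (a duplicated signal) make $S'S$
singular; a ridge of $10^{-6}\,\overline{\mathrm{diag}}$ is added, which
shares the weight evenly — only the *sum* of the collinear blocks'
$\delta$s is identifiable, and it is that sum (near 1, not 2) that
removes the double counting. With no cross-block LD, $\delta \to 1$ as
$n_\mathrm{ref}$ grows; at finite $n_\mathrm{ref}$ each $\hat\delta_b$
carries noise of roughly $\sqrt{B-1}/\sqrt{n_\mathrm{ref}}$ from sampling
error in the cross-block score correlations.

## Data handling

* Harmonization restricts to shared variants, reorders to the panel,
  sign-flips effects reported on the panel's allele 2, and drops
  strand-ambiguous palindromic (A/T, C/G) variants — the conservative
  default for summary data of unknown strand. It is idempotent.
* QC removes variants with > 1% missingness, mean-imputes the remainder,
  and greedily prunes within a 200-variant window (step 50) until no
  retained pair exceeds $r^2 = 0.95$, keeping the member of a violating
  pair with the smaller GWAS p-value when p-values are available and the
  earlier position otherwise. The window scan is deterministic; only the
  threshold is a modelling choice. When no validation data exist to
  supply p-values, panel-only pruning (positional tie-break) is used —
  the p-value rule is preferred when available because it retains the
  variants most likely to carry signal.
* Missing `eaf` columns are filled from reference-panel frequencies, the
  only alternative source available for the $X'y$ construction.
* The clumping + p-value thresholding baseline uses a 250 kb window
  (configurable), the standard software default; thresholds follow the
  usual grids ($r^2 \in \{0.2, 0.5, 0.8\}$,
  $p \in \{5\times10^{-8}, 10^{-5}, 10^{-4}, 10^{-3}, 0.0015, \dots,
  0.995\}$).
* Evaluation reports ROC AUC with a 95% CI from 2,000 stratified bootstrap
  replicates (cases and controls resampled separately, via pROC) for
  binary outcomes, and squared Pearson correlation on the observed scale
  for $r^2$ — no liability-scale conversion is attempted, and the label
  says so.

## The synthetic-data generator

`sim_config()`/`simulate_genotypes()` draw diploid genotypes from a
latent-Gaussian threshold model: each haplotype is an AR(1) Gaussian
process along the chromosome with step correlation `rho_within` inside
blocks, `rho_cross` at block boundaries, and 0 across chromosomes,
thresholded at a per-variant allele frequency drawn from `maf_range`. Two
independent haplotypes per individual give Hardy–Weinberg genotypes with
controllable short- and long-range LD; a `duplicate_block` mode copies one
block's latents onto a distant block to emulate MHC-like long-range LD.
Traits follow an additive model with `n_causal` effects scaled so the
genetic score explains exactly `h2` of unit variance; binary traits
threshold the liability at the chosen prevalence. Defaults
(`n_train = 3000`, `n_ref = 2000`, `n_test = 1000`, `P = 500` in blocks of
100, `rho_within = 0.5`, 20 causal variants, `h2 = 0.5`) are the reference
conditions the test suite exercises end to end; they are small enough for
minutes-scale runs while leaving per-causal-variant association z-scores
around 8–9 when effects are equal-sized, i.e. genuinely detectable.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: population structure and relatedness,
realistic recombination-driven LD decay, allele-frequency spectra,
imputation noise, strand errors, or between-cohort heterogeneity of
meta-analysed summaries. The generator's causal effects default to
Gaussian draws; note that under Gaussian effects a sizeable fraction of
causal variants fall below detectability at these sample sizes, so
recovery-style checks in the tests use equal-magnitude effects (each
causal variant explaining `h2 / n_causal` of variance) to keep the target
information-theoretically attainable.

## Problem sizes in the test suite

Unit tests run on blocks of 2–20 variants and panels of a few hundred
individuals. The deeper checks use: 200,000 iterations on a 6-variant
block against exact enumeration; 150,000 iterations for prior recovery at
$P = 20$; the default 500-variant, 5-block configuration for the
orthogonality ($\delta \approx 1$), duplicated-block, and end-to-end
recovery checks, with 8,000–20,000 sampler iterations per block — enough
for stable posterior means at these block sizes while keeping the whole
suite under a minute of compute.

## Known limitations

* The $X'y$ reconstruction inherits the HWE-variance approximation
  ($\sim 1/\sqrt{n}$ relative error) and assumes the summary effects,
  frequencies, and the reference panel describe the same population.
* Binary traits are handled through the linear approximation above, not an
  exact logistic likelihood.
* Each $\hat\delta_b$ is noisy at small reference panels (see above);
  interpret individual $\delta$s cautiously when block scores are highly
  collinear or when a block is essentially null — a noise-dominated block
  score has a tiny variance, and its $\delta$ (a ratio involving that
  variance) can be large in magnitude even though the block's *absolute*
  contribution to the final score stays bounded.
* INDELs, multi-allelic sites, X-chromosome dosage conventions, and
  summary-statistic imputation are out of scope.
* Tuning $\lambda$ on the evaluation data (as done when no third cohort is
  available) carries the usual risk of optimism; use an independent
  validation set when one exists.
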