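#' Sparsity and variance priors for the block model
#'
#' The proportion of variants with nonzero effects carries a
#' `Beta(1, lambda * P)` prior, integrated out analytically into a
#' beta-binomial mass over selections (see [log_model_prior()]); the effect
#' standard deviation has a `Unif(0.05, 2)` prior and the residual variance
#' an `Inv-Gamma(0.01, 0.01)` prior.
#'
#' @param lambda sparsity hyper-parameter, > 0. Under this prior the
#'   marginal prior odds that any given variant has an effect are
#'   `1 / (lambda * P)`, while the prior odds of at least one effect are
#'   constant at `1 / lambda`.
#' @param sigma_beta_min,sigma_beta_max support of the uniform prior on the
#'   effect standard deviation.
#' @param ig_a,ig_b inverse-gamma shape/scale for the residual variance.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(lambda = 0.01, sigma_beta_min = 0.05,
                         sigma_beta_max = 2, ig_a = 0.01, ig_b = 0.01) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (!(sigma_beta_min > 0 && sigma_beta_min < sigma_beta_max))
    stop("need 0 < sigma_beta_min < sigma_beta_max", call. = FALSE)
  structure(list(lambda = lambda, sigma_beta_min = sigma_beta_min,
                 sigma_beta_max = sigma_beta_max, ig_a = ig_a, ig_b = ig_b),
            class = "prior_config")
}

#' Reconstruct X'y from univariate summary statistics
#'
#' For mean-centred trait and genotypes, the univariate OLS estimate
#' satisfies `beta_p = x_p'y / x_p'x_p`, so each element of `X'y` is
#' recovered as `beta_p * n * 2 f_p (1 - f_p)`, using the Hardy-Weinberg
#' genotype variance `2 f (1 - f)` as the only frequency-based estimate of
#' `x_p'x_p / n` available from summary data.
#'
#' @param beta per-variant univariate effects (linear scale).
#' @param eaf effect-allele frequencies in (0, 1).
#' @param n GWAS sample size (scalar or per-variant).
#' @param xtx_diag optional per-variant `x_p'x_p` values to use instead of
#'   the Hardy-Weinberg approximation `n * 2 f (1 - f)`; with in-sample
#'   values the reconstruction is exact.
#' @return numeric vector, same length as `beta`.
#' @export
construct_xty <- function(beta, eaf, n, xtx_diag = NULL) {
  if (is.null(xtx_diag)) {
    if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
      stop("eaf must lie strictly in (0, 1)", call. = FALSE)
    xtx_diag <- n * 2 * eaf * (1 - eaf)
  }
  beta * xtx_diag
}

#' Map a log odds ratio to an approximate linear-scale effect
#'
#' For binary traits the block model needs the univariate effects a linear
#' regression of the (standardized) 0/1 outcome would have estimated. These
#' are recovered from the association z-score: `z / sqrt(n * 2 f (1 - f))`,
#' with `z = log_or / se`. Flipping the effect allele flips the sign only.
#'
#' @param log_or univariate log odds ratio(s).
#' @param se standard error(s) of the log-OR, > 0.
#' @param eaf effect-allele frequency in (0, 1).
#' @param n GWAS sample size.
#' @return approximate linear-scale univariate effect(s).
#' @export
binary_to_linear <- function(log_or, se, eaf, n) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (any(eaf <= 0) || any(eaf >= 1))
    stop("eaf must lie strictly in (0, 1)", call. = FALSE)
  (log_or / se) / sqrt(n * 2 * eaf * (1 - eaf))
}

#' Per-configuration log prior mass over variant selections
#'
#' Integrating the `Beta(1, lambda * P)` prior on the inclusion proportion
#' out of the independent-Bernoulli selection model gives a beta-binomial
#' mass for each selection configuration that depends on the configuration
#' only through its size `k`:
#' `log B(k + 1, P - k + lambda P) - log B(1, lambda P)`.
#'
#' @param k number of selected variants, `0 <= k <= P`.
#' @param P block size.
#' @param lambda sparsity hyper-parameter, > 0.
#' @return log prior mass of one configuration of size `k` (the masses of
#'   all `2^P` configurations sum to one).
#' @export
log_model_prior <- function(k, P, lambda) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (any(k < 0) || any(k > P)) stop("need 0 <= k <= P", call. = FALSE)
  lbeta(k + 1, P - k + lambda * P) - lbeta(1, lambda * P)
}

#' Build per-block sufficient statistics for the transformed likelihood
#'
#' Computes the plug-in `X'X` from mean-centred reference dosages, rescaled
#' by `n_gwas / n_ref` so that likelihood weight reflects the GWAS sample
#' size, reconstructs `X'y` from the univariate effects via
#' [construct_xty()], factorizes `X'X = L'L` (upper-triangular Cholesky,
#' with a single ridge-jitter retry of `1e-6 * mean(diag)` on failure), and
#' transforms to `z = L'^-1 X'y` so that the model becomes a standard
#' regression with independent Gaussian errors, `z ~ N(L beta, sigma^2 I)`.
#'
#' @param stats harmonized [summary_stats()] slice for the block (linear
#'   scale; map binary traits with [binary_to_linear()] first).
#' @param panel matching [reference_panel()] slice.
#' @param n_gwas GWAS sample size; defaults to the median of `stats$n`.
#' @param block_label label used in error messages.
#' @return an object of class `block_data` with fields `xty`, `xtx`, `L`,
#'   `z`, `n`, `variant_ids`, `p`.
#' @export
build_block_data <- function(stats, panel, n_gwas = NULL,
                             block_label = "block") {
  p <- nrow(stats)
  if (p != nrow(panel$variants) ||
      !all(stats$variant_id == panel$variants$variant_id))
    stop("stats and panel slices must cover the same variants in order",
         call. = FALSE)
  if (p > panel$n_ref)
    stop("block size ", p, " exceeds reference panel size ", panel$n_ref,
         " (full-rank X'X impossible)", call. = FALSE)
  if (is.null(n_gwas)) n_gwas <- stats::median(stats$n)

  gc <- scale(panel$genotypes, center = TRUE, scale = FALSE)
  xtx <- crossprod(gc) * (n_gwas / panel$n_ref)
  xty <- construct_xty(stats$beta, stats$eaf, n_gwas)

  # rank deficiency (e.g. duplicated variants surviving pruning) is a
  # data defect, not a round-off problem: refuse rather than regularize
  if (p > 1 && rcond(xtx) < 1e-12)
    stop("degenerate block '", block_label,
         "': X'X is rank deficient (p = ", p, ", n_ref = ", panel$n_ref,
         ")", call. = FALSE)
  L <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(L)) {
    jit <- 1e-6 * mean(diag(xtx))
    xtx_j <- xtx + diag(jit, p)
    L <- tryCatch(chol(xtx_j), error = function(e) NULL)
    if (is.null(L))
      stop("degenerate block '", block_label,
           "': X'X not positive definite even after ridge jitter",
           call. = FALSE)
    xtx <- xtx_j
    bp_msg("build_block_data: applied ridge jitter %.3g in %s", jit,
           block_label)
  }
  z <- backsolve(L, xty, transpose = TRUE)
  structure(list(xty = xty, xtx = xtx, L = L, z = z, n = n_gwas,
                 variant_ids = stats$variant_id, p = p),
            class = "block_data")
}

#' Log likelihood of the Cholesky-transformed block model
#'
#' Evaluates `sum_p log N(z_p | (L beta)_p, sigma^2)` with all constant
#' terms in `sigma^2` retained, so the value is valid for residual-variance
#' updates. Equals the untransformed multivariate Gaussian log density of
#' `X'y ~ MVN(X'X beta, X'X sigma^2)` plus the beta-independent Jacobian
#' `log|det L|`.
#'
#' @param state a [model_state()].
#' @param block a [build_block_data()] result.
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(state, block) {
  if (state$sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  r <- block$z - as.vector(block$L %*% state$beta)
  sum(dnorm(r, 0, sqrt(state$sigma2), log = TRUE))
}
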