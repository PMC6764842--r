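#' Configuration for the synthetic GWAS generator
#'
#' The generator draws diploid genotypes from a latent-Gaussian threshold
#' model: each haplotype has a latent AR(1) Gaussian process along the
#' chromosome with step correlation `rho_within` inside blocks and
#' `rho_cross` across adjacent block boundaries (0 across chromosomes),
#' thresholded at the allele frequency. This gives Hardy-Weinberg
#' genotypes with controllable short-range (within-block) and long-range
#' (cross-block) LD, the two regimes the two-step model distinguishes. A
#' `duplicate_block` mode copies one block's latents onto a distant block,
#' emulating MHC-like long-range LD in which the same signal is visible in
#' two separated regions.
#'
#' @param n_train,n_ref,n_test panel sizes (training GWAS, LD reference,
#'   test set).
#' @param P total number of variants.
#' @param block_size variants per block (also used for the LD structure).
#' @param rho_within latent adjacent-variant correlation inside blocks.
#' @param rho_cross latent correlation linking the last variant of one
#'   block to the first of the next.
#' @param maf_range allele-frequency range, drawn uniformly per variant.
#' @param n_causal number of causal variants.
#' @param h2 heritability of the simulated trait in `[0, 1)`.
#' @param binary simulate a binary trait by liability threshold?
#' @param prevalence case prevalence for binary traits.
#' @param n_chrom number of (equally sized) chromosomes.
#' @param duplicate_block optional `c(src, dst)` block indices: block
#'   `dst`'s latents are replaced by a copy of block `src`'s.
#' @param seed RNG seed; all three panels and the trait derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_train = 3000, n_ref = 2000, n_test = 1000, P = 500,
                       block_size = 100, rho_within = 0.5, rho_cross = 0,
                       maf_range = c(0.05, 0.5), n_causal = 20, h2 = 0.5,
                       binary = FALSE, prevalence = 0.1, n_chrom = 1,
                       duplicate_block = NULL, seed = 42) {
  if (rho_within < 0 || rho_within >= 1 || rho_cross < 0 || rho_cross >= 1)
    stop("rho_within and rho_cross must lie in [0, 1)", call. = FALSE)
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)", call. = FALSE)
  if (n_causal > P) stop("n_causal cannot exceed P", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (!is.null(duplicate_block) && length(duplicate_block) != 2)
    stop("duplicate_block must be c(src, dst)", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# per-variant chromosome labels: P split into n_chrom contiguous runs
sim_chrom_labels <- function(P, n_chrom) {
  sizes <- diff(round(seq(0, P, length.out = n_chrom + 1)))
  rep(as.character(seq_len(n_chrom)), sizes)
}

# AR(1) step correlations along the variant sequence
sim_step_rho <- function(config, chrom) {
  P <- config$P
  r <- numeric(P)
  if (P > 1) {
    new_block <- (seq_len(P) - 1) %% config$block_size == 0
    r[2:P] <- ifelse(new_block[2:P], config$rho_cross, config$rho_within)
    r[c(FALSE, chrom[2:P] != chrom[1:(P - 1)])] <- 0
  }
  r
}

# one n x P latent matrix following the AR(1) structure
sim_latents <- function(n, r, config) {
  P <- length(r)
  M <- matrix(rnorm(n * P), n, P)
  X <- M
  for (j in seq_len(P)[-1])
    X[, j] <- r[j] * X[, j - 1] + sqrt(1 - r[j]^2) * M[, j]
  if (!is.null(config$duplicate_block)) {
    src <- block_cols(config, config$duplicate_block[1])
    dst <- block_cols(config, config$duplicate_block[2])
    stopifnot(length(src) == length(dst))
    X[, dst] <- X[, src]
  }
  X
}

block_cols <- function(config, b) {
  s <- (b - 1) * config$block_size + 1
  s:min(s + config$block_size - 1, config$P)
}

#' Simulate train/ref/test genotype panels with block-structured LD
#'
#' Draws the three panels independently from the one LD structure defined
#' by `config` (see [sim_config()]). Dosages are hard calls in
#' `{0, 1, 2}`, counting the allele-1 ("A"-side) allele whose frequency
#' was drawn from `maf_range`.
#'
#' @param config a [sim_config()].
#' @param keep_latents attach each panel's first-haplotype latent matrix as
#'   attribute `"latents"` (for calibration tests).
#' @return `list(train = , ref = , test = )` of [reference_panel()]
#'   objects, with the drawn `mafs` and `config` attached.
#' @export
simulate_genotypes <- function(config, keep_latents = FALSE) {
  set.seed(config$seed)
  P <- config$P
  chrom <- sim_chrom_labels(P, config$n_chrom)
  r <- sim_step_rho(config, chrom)
  mafs <- runif(P, config$maf_range[1], config$maf_range[2])
  if (!is.null(config$duplicate_block)) {
    src <- block_cols(config, config$duplicate_block[1])
    dst <- block_cols(config, config$duplicate_block[2])
    mafs[dst] <- mafs[src]
  }
  thr <- qnorm(1 - mafs)

  allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                         ncol = 2, byrow = TRUE)
  ap <- allele_pairs[(seq_len(P) - 1) %% 4 + 1, , drop = FALSE]
  pos_in_chrom <- stats::ave(seq_len(P), chrom, FUN = seq_along)
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(P)), chrom = chrom,
    pos = pos_in_chrom * 2000L, a1 = ap[, 1], a2 = ap[, 2],
    stringsAsFactors = FALSE)

  draw_panel <- function(n) {
    h1 <- sim_latents(n, r, config)
    h2 <- sim_latents(n, r, config)
    g <- (sweep(h1, 2, thr, ">") + 0) + (sweep(h2, 2, thr, ">") + 0)
    panel <- reference_panel(g, variants)
    if (keep_latents) attr(panel, "latents") <- h1
    panel
  }
  out <- list(train = draw_panel(config$n_train),
              ref = draw_panel(config$n_ref),
              test = draw_panel(config$n_test))
  out$mafs <- mafs
  out$config <- config
  out
}

#' Simulate a trait on a genotype panel
#'
#' Draws `n_causal` effects, rescales them so the genetic score explains
#' exactly `h2` of unit total variance in this panel, and adds Gaussian
#' noise; binary traits are thresholded from the continuous liability at
#' the configured prevalence. Uses its own seed stream derived from
#' `config$seed`, so two configurations sharing a seed and causal set get
#' identical traits whenever the causal genotype columns are identical.
#'
#' The causal positions, the effect values, and the environmental noise are
#' drawn from three separate streams derived from `config$seed`, so a trait
#' simulated on a second panel with the same configuration (e.g. a test
#' set) shares the causal architecture while its noise stays independent of
#' the training noise.
#'
#' @param panel a [reference_panel()] (typically the training panel).
#' @param config a [sim_config()].
#' @param causal_idx optional fixed causal variant indices; drawn uniformly
#'   at random when `NULL`.
#' @param beta_true optional length-P per-allele effect vector, used as-is
#'   (no heritability rescaling); pass a training run's `beta_true` to
#'   simulate the identical architecture on a held-out panel.
#' @return `list(y = outcome, liability = , g = genetic score,
#'   beta_true = length-P effect vector, causal = indices)`.
#' @export
simulate_trait <- function(panel, config, causal_idx = NULL,
                           beta_true = NULL) {
  P <- ncol(panel$genotypes)
  n <- nrow(panel$genotypes)
  if (is.null(beta_true)) {
    if (is.null(causal_idx)) {
      set.seed(derive_seed(config$seed, 260901))
      causal_idx <- sort(sample.int(P, config$n_causal))
    }
    beta_true <- numeric(P)
    if (config$h2 > 0 && length(causal_idx) > 0) {
      set.seed(derive_seed(config$seed, 260902))
      b_raw <- rnorm(length(causal_idx))
      gc <- scale(panel$genotypes[, causal_idx, drop = FALSE],
                  center = TRUE, scale = FALSE)
      scl <- sqrt(config$h2) / sd(as.vector(gc %*% b_raw))
      beta_true[causal_idx] <- b_raw * scl
    }
  } else {
    stopifnot(length(beta_true) == P)
    causal_idx <- which(beta_true != 0)
  }
  g <- if (length(causal_idx)) {
    gc <- scale(panel$genotypes[, causal_idx, drop = FALSE], center = TRUE,
                scale = FALSE)
    as.vector(gc %*% beta_true[causal_idx])
  } else numeric(n)
  set.seed(derive_seed(config$seed, 260903 + n))
  liability <- g + rnorm(n, 0, sqrt(1 - config$h2))
  y <- if (config$binary)
    as.numeric(liability > qnorm(1 - config$prevalence)) else liability
  list(y = y, liability = liability, g = g, beta_true = beta_true,
       causal = causal_idx)
}

#' Univariate GWAS summaries from individual-level data
#'
#' Emulates what a GWAS consortium reports: one-at-a-time per-variant
#' regressions. Continuous traits use closed-form OLS on centred data;
#' binary traits use per-variant logistic regression (log odds ratios).
#' Constant variants are dropped with a warning.
#'
#' @param panel a [reference_panel()].
#' @param y outcome vector (0/1 when `binary`).
#' @param binary fit logistic instead of linear regressions?
#' @return a [summary_stats()] object (effect allele = panel allele 1,
#'   `eaf` = empirical allele-1 frequency, `n` = number of individuals).
#' @export
compute_univariate_summaries <- function(panel, y, binary = FALSE) {
  g <- panel$genotypes
  n <- nrow(g)
  const <- apply(g, 2, function(x) max(x, na.rm = TRUE) ==
                   min(x, na.rm = TRUE))
  if (any(const)) {
    warning(sum(const), " constant variant(s) dropped from summaries",
            call. = FALSE)
    panel <- panel_subset(panel, which(!const))
    g <- panel$genotypes
  }
  if (binary) {
    co <- t(vapply(seq_len(ncol(g)), function(j) {
      X <- cbind(1, g[, j])
      fit <- glm.fit(X, y, family = binomial())
      mu <- fit$fitted.values
      info <- crossprod(X * sqrt(mu * (1 - mu)))
      se <- sqrt(diag(solve(info)))
      c(fit$coefficients[2], se[2])
    }, c(0, 0)))
    beta <- co[, 1]; se <- co[, 2]
  } else {
    xc <- scale(g, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    beta <- colSums(xc * yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  }
  summary_stats(
    variant_id = panel$variants$variant_id, chrom = panel$variants$chrom,
    pos = panel$variants$pos, effect_allele = panel$variants$a1,
    other_allele = panel$variants$a2, beta = beta, se = se,
    eaf = colMeans(g) / 2, n = n, is_binary = binary)
}
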