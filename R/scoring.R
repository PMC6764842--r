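#' Apply PRS weights to genotypes
#'
#' Computes `PRS_i = sum_p dosage_ip * weight_p` after matching weights to
#' the genotype panel by variant ID and re-harmonizing alleles: where the
#' panel counts the weight's non-effect allele the contribution is flipped
#' exactly (`w * (2 - x)`), so scores are invariant to the allele frame.
#' Weights for variants absent from the panel are skipped with a reported
#' count.
#'
#' @param panel a [reference_panel()] (missing dosages mean-imputed).
#' @param weights a `weight_set`.
#' @param center use mean-centred dosages (shifts every score equally).
#' @return numeric vector of per-individual scores.
#' @export
score_individuals <- function(panel, weights, center = FALSE) {
  idx <- match(weights$variant_id, panel$variants$variant_id)
  absent <- is.na(idx)
  if (all(absent))
    stop("no weight variants found in the genotype panel", call. = FALSE)
  if (any(absent))
    bp_msg("score_individuals: %d weight variant(s) missing from genotypes",
           sum(absent))
  w <- weights$weight[!absent]
  idx <- idx[!absent]
  a1 <- panel$variants$a1[idx]
  a2 <- panel$variants$a2[idx]
  ea <- weights$effect_allele[!absent]
  same <- ea == a1
  flip <- ea == a2
  if (any(!same & !flip)) {
    bp_msg("score_individuals: %d variant(s) dropped for allele mismatch",
           sum(!same & !flip))
    keepv <- same | flip
    w <- w[keepv]; idx <- idx[keepv]; same <- same[keepv]; flip <- flip[keepv]
  }
  g <- panel$genotypes[, idx, drop = FALSE]
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0))
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
  }
  w_signed <- ifelse(same, w, -w)
  offset <- 2 * sum(w[flip])
  if (center) {
    g <- scale(g, center = TRUE, scale = FALSE)
    as.vector(g %*% w_signed)
  } else {
    as.vector(g %*% w_signed) + offset
  }
}

#' Evaluate a polygenic score against an outcome
#'
#' Binary outcomes: ROC AUC via the rank statistic (pROC) with a 95%
#' confidence interval from stratified bootstrap replicates (cases and
#' controls resampled separately), plus the squared Pearson correlation on
#' the observed scale. Continuous outcomes: squared Pearson correlation.
#'
#' @param prs per-individual scores.
#' @param outcome 0/1 vector (binary) or numeric vector (continuous).
#' @param n_boot bootstrap replicates for the AUC CI (2000 by default).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return for binary outcomes `list(type = "binary", auc, auc_ci, r2,
#'   n_boot)`; for continuous `list(type = "continuous", r2)`.
#' @export
evaluate_prs <- function(prs, outcome, n_boot = 2000, conf = 0.95,
                         seed = NULL) {
  if (length(prs) != length(outcome))
    stop("prs and outcome lengths differ", call. = FALSE)
  if (all(outcome %in% c(0, 1))) {
    if (length(unique(outcome)) < 2)
      stop("AUC undefined: outcome has a single class", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    roc <- pROC::roc(response = outcome, predictor = prs, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    ci <- pROC::ci.auc(roc, method = "bootstrap", boot.n = n_boot,
                       boot.stratified = TRUE, conf.level = conf)
    list(type = "binary", auc = as.numeric(pROC::auc(roc)),
         auc_ci = c(ci[1], ci[3]), r2 = cor(prs, outcome)^2,
         n_boot = n_boot)
  } else {
    list(type = "continuous", r2 = cor(prs, outcome)^2)
  }
}

# point AUC without bootstrap, for tuning loops
auc_point <- function(prs, outcome) {
  as.numeric(pROC::auc(pROC::roc(response = outcome, predictor = prs,
                                 quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Select the sparsity hyper-parameter on validation data
#'
#' Scores the validation genotypes with each candidate's weights and
#' returns the candidate maximizing validation AUC (binary outcome) or
#' r-squared (continuous). Ties break toward the sparser weight set (fewer
#' nonzero weights). The recommended grid is
#' `lambda in {0.001, 0.01, 0.1, 1}`.
#'
#' @param lambdas numeric vector of candidate values.
#' @param weight_sets list of `weight_set` objects, one per candidate.
#' @param val_panel validation [reference_panel()].
#' @param val_outcome validation phenotype vector.
#' @return `list(lambda, index, weights, metrics)` where `metrics` is a
#'   per-candidate data.frame.
#' @export
select_lambda <- function(lambdas, weight_sets, val_panel, val_outcome) {
  if (length(lambdas) == 0) stop("empty candidate list", call. = FALSE)
  if (length(lambdas) != length(weight_sets))
    stop("one weight set per lambda candidate required", call. = FALSE)
  binary <- all(val_outcome %in% c(0, 1))
  metric <- vapply(weight_sets, function(ws) {
    prs <- score_individuals(val_panel, ws)
    if (binary) auc_point(prs, val_outcome) else cor(prs, val_outcome)^2
  }, 0)
  nnz <- vapply(weight_sets, function(ws) sum(ws$weight != 0), 0L)
  best <- which(metric == max(metric))
  if (length(best) > 1) best <- best[which.min(nnz[best])]
  list(lambda = lambdas[best], index = best, weights = weight_sets[[best]],
       metrics = data.frame(lambda = lambdas, metric = metric,
                            metric_type = if (binary) "auc" else "r2",
                            n_nonzero = nnz))
}

#' Clumping + p-value thresholding baseline scores
#'
#' The standard baseline: for each r-squared threshold, greedily clump the
#' variants -- repeatedly take the most significant unremoved variant as an
#' index and remove all variants within `window_kb` on the same chromosome
#' whose squared correlation with it (in the panel) exceeds the threshold
#' -- then, for each p-value threshold, keep the surviving variants with
#' `p <= threshold`, weighted by their univariate effects.
#'
#' @param stats harmonized [summary_stats()].
#' @param panel matching [reference_panel()].
#' @param p_thresholds p-value grid (default `{5e-8, 1e-5, 1e-4, 1e-3,
#'   0.0015, 0.0025, ..., 0.995}`).
#' @param r2_clump r-squared thresholds (default `{0.2, 0.5, 0.8}`).
#' @param window_kb clumping window in kilobases.
#' @return nested list `result[[r2 label]][[p label]]` of `weight_set`
#'   objects, with a `summary` data.frame attribute (variant counts per
#'   setting).
#' @export
baseline_threshold_and_clump <- function(stats, panel,
                                         p_thresholds = c(5e-8, 1e-5, 1e-4,
                                                          1e-3,
                                                          seq(0.0015, 0.9955,
                                                              by = 0.001)),
                                         r2_clump = c(0.2, 0.5, 0.8),
                                         window_kb = 250) {
  stopifnot(nrow(stats) == nrow(panel$variants))
  pvals <- 2 * pnorm(-abs(stats$beta / stats$se))
  g <- panel$genotypes
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0))
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
  }
  chrom <- as.character(stats$chrom)
  pos <- stats$pos
  window <- window_kb * 1000

  clump_once <- function(r2_thr) {
    removed <- logical(length(pvals))
    index <- logical(length(pvals))
    for (i in order(pvals)) {
      if (removed[i] || index[i]) next
      index[i] <- TRUE
      cand <- which(!removed & !index & chrom == chrom[i] &
                      abs(pos - pos[i]) <= window)
      if (length(cand)) {
        r2 <- as.vector(cor(g[, i], g[, cand, drop = FALSE]))^2
        removed[cand[r2 > r2_thr]] <- TRUE
      }
    }
    which(index)
  }

  out <- list()
  counts <- NULL
  for (r2 in r2_clump) {
    surv <- clump_once(r2)
    by_p <- list()
    for (pt in p_thresholds) {
      keep <- surv[pvals[surv] <= pt]
      ws <- data.frame(variant_id = stats$variant_id[keep],
                       effect_allele = stats$effect_allele[keep],
                       weight = stats$beta[keep], stringsAsFactors = FALSE)
      class(ws) <- c("weight_set", "data.frame")
      by_p[[sprintf("p_%g", pt)]] <- ws
      counts <- rbind(counts, data.frame(r2 = r2, p = pt,
                                         n_variants = length(keep)))
    }
    out[[sprintf("r2_%g", r2)]] <- by_p
  }
  attr(out, "summary") <- counts
  out
}
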