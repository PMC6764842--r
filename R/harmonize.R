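#' Harmonize summary statistics with a reference panel
#'
#' Restricts both inputs to their shared variants, reorders the statistics
#' to the panel's variant order, and puts effects on the panel's allele
#' frame: where the stats effect allele equals the panel's allele 2, `beta`
#' is sign-flipped and `eaf` replaced by `1 - eaf`. Strand-ambiguous
#' palindromic variants (A/T, C/G) are dropped, as are variants whose
#' alleles match the panel in neither orientation. Missing `eaf` values are
#' filled from the panel allele-1 frequency.
#'
#' Harmonization is idempotent: applying it to already-harmonized inputs is
#' a no-op.
#'
#' @param stats a [summary_stats()] object.
#' @param panel a [reference_panel()].
#' @return `list(stats = , panel = )` with identical variant sets and order.
#' @export
harmonize <- function(stats, panel) {
  v <- panel$variants
  common <- intersect(v$variant_id, stats$variant_id)
  if (length(common) == 0)
    stop("no variants shared between summary statistics and panel",
         call. = FALSE)
  keep_panel <- which(v$variant_id %in% common)
  v <- v[keep_panel, , drop = FALSE]
  st <- stats[match(v$variant_id, stats$variant_id), , drop = FALSE]

  pal <- paste0(st$effect_allele, st$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  same <- st$effect_allele == v$a1 & st$other_allele == v$a2
  flip <- st$effect_allele == v$a2 & st$other_allele == v$a1
  usable <- !pal & (same | flip)
  n_pal <- sum(pal); n_mismatch <- sum(!pal & !same & !flip)
  if (n_pal > 0)
    bp_msg("harmonize: dropped %d strand-ambiguous palindromic variant(s)",
           n_pal)
  if (n_mismatch > 0)
    bp_msg("harmonize: dropped %d variant(s) with unmatchable alleles",
           n_mismatch)
  if (!any(usable))
    stop("no variants left after allele matching", call. = FALSE)

  st <- st[usable, , drop = FALSE]
  flip <- flip[usable]
  keep_panel <- keep_panel[usable]
  st$beta[flip] <- -st$beta[flip]
  st$eaf[flip] <- 1 - st$eaf[flip]
  st$effect_allele[flip] <- panel$variants$a1[keep_panel][flip]
  st$other_allele[flip] <- panel$variants$a2[keep_panel][flip]

  out_panel <- panel_subset(panel, keep_panel)
  miss_eaf <- is.na(st$eaf)
  if (any(miss_eaf)) {
    panel_freq <- colMeans(out_panel$genotypes, na.rm = TRUE) / 2
    st$eaf[miss_eaf] <- panel_freq[miss_eaf]
    bp_msg("harmonize: filled %d missing eaf value(s) from panel frequencies",
           sum(miss_eaf))
  }
  rownames(st) <- NULL
  attr(st, "is_binary") <- attr(stats, "is_binary")
  class(st) <- c("summary_stats", "data.frame")
  validate_summary_stats(st)
  list(stats = st, panel = out_panel)
}

#' Quality control and LD pruning of a reference panel
#'
#' Removes variants with missingness above `missing_max`, mean-imputes the
#' remaining missing dosages, drops constant columns, and then greedily
#' prunes within a sliding window so that no retained pair of variants in a
#' window has squared correlation above `r2_max`. In each violating pair
#' the variant with the larger GWAS p-value (when `pvalues` is supplied) or
#' the later position is removed.
#'
#' @param panel a [reference_panel()].
#' @param missing_max maximum tolerated per-variant missing rate.
#' @param r2_max maximum tolerated pairwise r-squared among kept variants.
#' @param window,step sliding-window size and step, in variants.
#' @param pvalues optional per-variant p-values aligned to the panel, used
#'   to decide which member of a correlated pair to keep.
#' @return `list(panel = pruned imputed panel, kept = variant ids,
#'   n_removed_missing = , n_removed_ld = )`.
#' @export
qc_and_prune <- function(panel, missing_max = 0.01, r2_max = 0.95,
                         window = 200, step = 50, pvalues = NULL) {
  g <- panel$genotypes
  miss <- colMeans(is.na(g))
  keep_miss <- miss <= missing_max
  n_removed_missing <- sum(!keep_miss)
  g <- g[, keep_miss, drop = FALSE]
  v <- panel$variants[keep_miss, , drop = FALSE]
  if (!is.null(pvalues)) pvalues <- pvalues[keep_miss]

  # mean-impute remaining missing dosages so correlation matrices are complete
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0)) {
      m <- mean(g[, j], na.rm = TRUE)
      g[is.na(g[, j]), j] <- m
    }
  }
  const <- apply(g, 2, function(x) max(x) == min(x))
  if (any(const)) {
    n_removed_missing <- n_removed_missing + sum(const)
    g <- g[, !const, drop = FALSE]
    v <- v[!const, , drop = FALSE]
    if (!is.null(pvalues)) pvalues <- pvalues[!const]
  }

  P <- ncol(g)
  keep <- rep(TRUE, P)
  if (P > 1 && r2_max < 1) {
    start <- 1
    repeat {
      win <- start:min(start + window - 1, P)
      cur <- win[keep[win]]
      if (length(cur) > 1) {
        C2 <- cor(g[, cur, drop = FALSE])^2
        diag(C2) <- 0
        repeat {
          mx <- which.max(C2)
          if (C2[mx] <= r2_max) break
          ij <- arrayInd(mx, dim(C2))
          a <- cur[ij[1]]; b <- cur[ij[2]]
          drop_var <- if (!is.null(pvalues)) {
            if (pvalues[a] > pvalues[b]) a else b
          } else max(a, b)
          keep[drop_var] <- FALSE
          di <- which(cur == drop_var)
          C2[di, ] <- 0; C2[, di] <- 0
        }
      }
      if (start + window - 1 >= P) break
      start <- start + step
    }
  }
  n_removed_ld <- sum(!keep)
  bp_msg("qc_and_prune: removed %d for missingness/constancy, %d for LD; %d kept",
         n_removed_missing, n_removed_ld, sum(keep))
  out <- reference_panel(g[, keep, drop = FALSE], v[keep, , drop = FALSE])
  list(panel = out, kept = out$variants$variant_id,
       n_removed_missing = n_removed_missing, n_removed_ld = n_removed_ld)
}
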