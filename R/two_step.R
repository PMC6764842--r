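#' Partition variants into contiguous blocks within chromosomes
#'
#' Splits the variant list into contiguous blocks of `block_size` (default
#' 100, the size the method was developed with). Blocks never straddle a
#' chromosome boundary; the trailing remainder on each chromosome forms a
#' smaller final block.
#'
#' @param variants `data.frame` with `chrom` and `pos`, sorted by
#'   (chromosome, position); chromosomes must be contiguous runs.
#' @param block_size target number of variants per block.
#' @return a list of integer index vectors of class `block_partition`.
#' @export
partition_blocks <- function(variants, block_size = 100) {
  chrom <- as.character(variants$chrom)
  pos <- variants$pos
  runs <- rle(chrom)
  if (anyDuplicated(runs$values))
    stop("variants are not grouped by chromosome", call. = FALSE)
  offsets <- cumsum(c(0, runs$lengths))
  blocks <- list()
  for (ci in seq_along(runs$values)) {
    idx <- (offsets[ci] + 1):(offsets[ci] + runs$lengths[ci])
    if (is.unsorted(pos[idx]))
      stop("positions not sorted within chromosome ", runs$values[ci],
           call. = FALSE)
    starts <- seq(1, length(idx), by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1, length(idx))
      blocks[[length(blocks) + 1]] <- idx[s:e]
    }
  }
  structure(blocks, block_size = block_size, class = "block_partition")
}

#' Step 1: fit every block independently
#'
#' Runs [run_block_sampler()] on each block of the partition. Each block
#' gets its own deterministic seed derived from `(config$seed, block
#' index)`, so results are identical whether blocks are run sequentially or
#' distributed over `workers` processes. Binary-trait effects are mapped to
#' the linear scale with [binary_to_linear()] before block construction. A
#' failure in any block aborts the whole run naming the block.
#'
#' @param stats harmonized [summary_stats()].
#' @param panel matching [reference_panel()] (same variants, same order).
#' @param partition a [partition_blocks()] result.
#' @param config a [sampler_config()].
#' @param workers number of parallel worker processes (forked; the result
#'   never depends on this number).
#' @return list of [run_block_sampler()] results, one per block, of class
#'   `step1_fit`.
#' @export
fit_step1 <- function(stats, panel, partition, config, workers = 1) {
  stopifnot(nrow(stats) == nrow(panel$variants))
  beta_lin <- if (isTRUE(attr(stats, "is_binary"))) {
    binary_to_linear(stats$beta, stats$se, stats$eaf, stats$n)
  } else stats$beta

  fit_one <- function(b) {
    idx <- partition[[b]]
    st <- stats[idx, , drop = FALSE]
    st$beta <- beta_lin[idx]
    bd <- build_block_data(st, panel_subset(panel, idx),
                           block_label = paste0("block ", b))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, b)
    run_block_sampler(bd, cfg)
  }
  wrapped <- function(b) {
    tryCatch(fit_one(b), error = function(e) {
      structure(list(block = b, message = conditionMessage(e)),
                class = "bp_block_failure")
    })
  }
  res <- if (workers > 1) {
    parallel::mclapply(seq_along(partition), wrapped, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(partition), wrapped)
  }
  failed <- vapply(res, function(x)
    inherits(x, "bp_block_failure") || inherits(x, "try-error"), TRUE)
  if (any(failed)) {
    b <- which(failed)[1]
    msg <- if (inherits(res[[b]], "bp_block_failure"))
      res[[b]]$message else as.character(res[[b]])
    stop("Step 1 failed in block ", b, ": ", msg, call. = FALSE)
  }
  structure(res, class = "step1_fit")
}

#' Block-level polygenic scores on the reference panel
#'
#' Column `b` is the score of block `b` for every reference individual,
#' `s_ib = sum_p x_ibp * beta_bp`, computed on mean-centred dosages.
#'
#' @param panel a [reference_panel()].
#' @param partition a [partition_blocks()] result.
#' @param block_weights list of per-block weight vectors (e.g.
#'   `posterior_mean_beta` from Step 1).
#' @return `n_ref x B` matrix of block scores.
#' @export
build_block_scores <- function(panel, partition, block_weights) {
  stopifnot(length(partition) == length(block_weights))
  B <- length(partition)
  S <- matrix(0, panel$n_ref, B)
  for (b in seq_len(B)) {
    idx <- partition[[b]]
    stopifnot(length(idx) == length(block_weights[[b]]))
    gc <- scale(panel$genotypes[, idx, drop = FALSE], center = TRUE,
                scale = FALSE)
    S[, b] <- as.vector(gc %*% block_weights[[b]])
  }
  S
}

#' Step-2 sufficient statistics S'S and S'y
#'
#' The block scores play the role the variants played in Step 1: `S'S` is
#' the plug-in cross-product of centred reference block scores rescaled to
#' the GWAS sample size, and `S'y` is built exactly as `X'y` was -- the
#' marginal effect of each block score times its sum of squares. By
#' construction every block score has marginal effect 1 on the trait (its
#' weights are already on the trait scale), so `S'y = diag(S'S)`.
#'
#' @param S_ref reference block-score matrix from [build_block_scores()].
#' @param n_gwas GWAS sample size.
#' @param n_ref reference panel size.
#' @return `list(StS = , Sty = , zero_blocks = )` where `zero_blocks`
#'   flags blocks whose score has (numerically) zero variance.
#' @export
build_sts_sty <- function(S_ref, n_gwas, n_ref) {
  sc <- scale(S_ref, center = TRUE, scale = FALSE)
  StS <- crossprod(sc) * (n_gwas / n_ref)
  Sty <- diag(StS)
  zero <- Sty <= 1e-12 * max(Sty, 1e-300)
  if (any(zero))
    warning(sum(zero), " block score(s) have zero variance; their delta ",
            "will be fixed to 0", call. = FALSE)
  list(StS = StS, Sty = Sty, zero_blocks = zero)
}

#' Step 2: maximum-likelihood cross-block adjustment
#'
#' Solves `S'S delta = S'y` -- the MLE of the regression of the trait on
#' the block scores implied by `S'y ~ MVN(S'S delta, S'S sigma2)`; the
#' residual variance profiles out of the estimate and no model selection is
#' performed at this level. Zero-variance blocks get `delta = 0`. A
#' numerically singular system (e.g. duplicated blocks in perfect LD) is
#' regularized with a ridge of `1e-6 * mean(diag)`.
#'
#' @param StS,Sty from [build_sts_sty()].
#' @param zero_blocks logical flags of excluded blocks (default: taken from
#'   near-zero diagonal entries).
#' @return numeric vector `delta` of length B.
#' @export
estimate_delta <- function(StS, Sty, zero_blocks = NULL) {
  B <- length(Sty)
  if (is.null(zero_blocks))
    zero_blocks <- diag(StS) <= 1e-12 * max(diag(StS), 1e-300)
  delta <- numeric(B)
  act <- which(!zero_blocks)
  if (length(act) == 0) return(delta)
  A <- StS[act, act, drop = FALSE]
  y <- Sty[act]
  sol <- NULL
  if (rcond(A) > 1e-10)
    sol <- tryCatch(solve(A, y), error = function(e) NULL)
  if (is.null(sol)) {
    warning("S'S numerically singular; applying ridge regularization",
            call. = FALSE)
    A <- A + diag(1e-6 * mean(diag(A)), length(act))
    sol <- solve(A, y)
  }
  delta[act] <- sol
  delta
}

#' Combine Step-1 weights with the Step-2 scaling
#'
#' The genome-wide weight of variant `p` in block `b` is
#' `delta_b * beta_bp`.
#'
#' @param block_weights list of per-block weight vectors.
#' @param delta per-block scaling from [estimate_delta()].
#' @param variants variant metadata aligned to the concatenated blocks
#'   (supplies `variant_id` and effect allele `a1`).
#' @return a `weight_set` data.frame: `variant_id`, `effect_allele`,
#'   `weight`, plus the `block` index.
#' @export
combine_weights <- function(block_weights, delta, variants) {
  stopifnot(length(block_weights) == length(delta))
  w <- unlist(lapply(seq_along(delta), function(b)
    delta[b] * block_weights[[b]]))
  blk <- rep(seq_along(delta), lengths(block_weights))
  stopifnot(length(w) == nrow(variants))
  out <- data.frame(variant_id = variants$variant_id,
                    effect_allele = variants$a1,
                    weight = as.numeric(w), block = blk,
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Fit the full two-step model
#'
#' Convenience orchestrator: partitions the (harmonized, pruned) variants,
#' fits every block by RJMCMC (Step 1), builds reference block scores,
#' estimates the cross-block scaling `delta` (Step 2), and combines into
#' genome-wide weights.
#'
#' @inheritParams fit_step1
#' @param block_size variants per block.
#' @return list of class `two_step_fit`: `weights` (genome-wide
#'   `weight_set` with posterior inclusion probabilities), `step1`,
#'   `partition`, `StS`, `Sty`, `delta`, `config`.
#' @export
fit_two_step <- function(stats, panel, config = sampler_config(),
                         block_size = 100, workers = 1) {
  partition <- partition_blocks(panel$variants, block_size)
  step1 <- fit_step1(stats, panel, partition, config, workers)
  bw <- lapply(step1, `[[`, "posterior_mean_beta")
  S <- build_block_scores(panel, partition, bw)
  n_gwas <- stats::median(stats$n)
  ss <- build_sts_sty(S, n_gwas, panel$n_ref)
  delta <- estimate_delta(ss$StS, ss$Sty, ss$zero_blocks)
  weights <- combine_weights(bw, delta, panel$variants)
  weights$pip <- unlist(lapply(step1, `[[`, "pip"))
  structure(list(weights = weights, step1 = step1, partition = partition,
                 StS = ss$StS, Sty = ss$Sty, delta = delta,
                 config = config),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  sizes <- vapply(x$step1, `[[`, 0, "posterior_mean_model_size")
  cat("two_step_fit:", nrow(x$weights), "variants in",
      length(x$partition), "blocks\n")
  cat("  lambda:", x$config$prior$lambda, "\n")
  cat("  posterior mean model size per block:",
      paste(sprintf("%.2f", sizes), collapse = ", "), "\n")
  cat("  delta range: [", sprintf("%.3f", min(x$delta)), ",",
      sprintf("%.3f", max(x$delta)), "]\n")
  invisible(x)
}

#' Write/read a PRS scoring file
#'
#' Tab-delimited `variant_id, effect_allele, weight`, consumable by
#' standard allelic-scoring tools.
#'
#' @param weights a `weight_set`.
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  write.table(weights[, c("variant_id", "effect_allele", "weight")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  out <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(out)))
  class(out) <- c("weight_set", "data.frame")
  out
}
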