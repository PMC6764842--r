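test_that("scores equal the matrix-vector product and respect alleles", {
  d <- small_dataset(P = 12, block_size = 6, n_ref = 200, seed = 71)
  panel <- d$panel
  set.seed(1)
  w <- data.frame(variant_id = panel$variants$variant_id,
                  effect_allele = panel$variants$a1,
                  weight = rnorm(12, 0, 0.3), stringsAsFactors = FALSE)
  class(w) <- c("weight_set", "data.frame")

  prs <- score_individuals(panel, w)
  expect_equal(prs, as.vector(panel$genotypes %*% w$weight))

  w0 <- w; w0$weight <- 0
  expect_true(all(score_individuals(panel, w0) == 0))

  w1 <- w0; w1$weight[3] <- 1
  expect_equal(score_individuals(panel, w1), panel$genotypes[, 3],
               ignore_attr = TRUE)

  # a weight re-expressed on the other allele is the same predictor: the
  # dosage-scale scores differ only by the constant 2w, and centred
  # scoring removes even that
  w_flip <- w
  w_flip$effect_allele[4] <- panel$variants$a2[4]
  w_flip$weight[4] <- -w$weight[4]
  expect_equal(score_individuals(panel, w_flip) + 2 * w$weight[4], prs,
               tolerance = 1e-12)
  expect_equal(score_individuals(panel, w_flip, center = TRUE),
               score_individuals(panel, w, center = TRUE),
               tolerance = 1e-12)

  # weights for absent variants are skipped; total disjointness is an error
  w_extra <- rbind(w, data.frame(variant_id = "nope", effect_allele = "A",
                                 weight = 5))
  class(w_extra) <- c("weight_set", "data.frame")
  expect_equal(score_individuals(panel, w_extra), prs)
  w_none <- w; w_none$variant_id <- paste0("x", seq_len(12))
  expect_error(score_individuals(panel, w_none), "no weight variants")
})

test_that("evaluation returns AUC with a sane bootstrap CI and exact r2", {
  y <- rep(c(0, 1), each = 50)
  prs <- c(rnorm(50, 0), rnorm(50, 10))  # perfectly separated
  # pROC warns that a CI of a perfect AUC is degenerate; that is the point
  ev <- suppressWarnings(evaluate_prs(prs, y, n_boot = 100, seed = 1))
  expect_equal(ev$auc, 1)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])

  # r2 of a perfectly predictive score is exactly 1
  yc <- rnorm(100)
  expect_equal(evaluate_prs(yc, yc)$r2, 1)

  # independent score: AUC near 1/2
  set.seed(4)
  y0 <- rbinom(10000, 1, 0.3)
  p0 <- rnorm(10000)
  expect_lt(abs(evaluate_prs(p0, y0, n_boot = 50, seed = 2)$auc - 0.5),
            0.02)

  expect_error(evaluate_prs(rnorm(10), rep(1, 10)), "single class")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(6)
  y <- rbinom(400, 1, 0.4)
  prs <- rnorm(400) + y
  a1 <- evaluate_prs(prs, y, n_boot = 50, seed = 1)$auc
  a2 <- evaluate_prs(exp(2 * prs), y, n_boot = 50, seed = 1)$auc
  expect_equal(a1, a2)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(8)
  make_ci <- function(n) {
    y <- rep(c(0, 1), each = n / 2)
    prs <- rnorm(n) + 0.8 * y
    ev <- evaluate_prs(prs, y, n_boot = 300, seed = 3)
    diff(ev$auc_ci)
  }
  expect_gt(make_ci(300), make_ci(4000))
})

test_that("lambda selection maximizes the validation metric", {
  d <- small_dataset(P = 10, block_size = 10, n_ref = 300, seed = 73)
  panel <- d$panel
  y <- as.vector(panel$genotypes %*% c(rep(0.5, 3), rep(0, 7))) +
    rnorm(panel$n_ref, 0, 0.5)
  good <- data.frame(variant_id = panel$variants$variant_id,
                     effect_allele = panel$variants$a1,
                     weight = c(rep(0.5, 3), rep(0, 7)))
  noise <- good; set.seed(2); noise$weight <- rnorm(10)
  sel <- select_lambda(c(0.1, 1), list(noise, good), panel, y)
  expect_equal(sel$lambda, 1)
  expect_equal(sel$metrics$metric_type[1], "r2")

  one <- select_lambda(5, list(good), panel, y)
  expect_equal(one$lambda, 5)

  # ties break toward the sparser candidate: an extra nonzero weight on a
  # variant absent from the panel changes no score but adds a nonzero
  bloated <- rbind(good, data.frame(variant_id = "zz", effect_allele = "A",
                                    weight = 1))
  class(bloated) <- class(good)
  tie <- select_lambda(c(1, 2), list(bloated, good), panel, y)
  expect_equal(tie$lambda, 2)

  expect_error(select_lambda(numeric(0), list(), panel, y), "empty")
})

test_that("clumping keeps the stronger of a correlated pair and nests in thresholding", {
  d <- small_dataset(P = 30, block_size = 30, n_train = 1500, n_ref = 400,
                     rho_within = 0.9, n_causal = 3, h2 = 0.4, seed = 75)
  res <- baseline_threshold_and_clump(d$stats, d$panel,
                                      p_thresholds = c(1e-3, 0.5, 1),
                                      r2_clump = c(0.2, 1))
  # r2 = 1 never clumps; p = 1 keeps everything
  expect_equal(nrow(res[["r2_1"]][["p_1"]]), 30)
  expect_equal(res[["r2_1"]][["p_1"]]$weight, d$stats$beta)
  # clumping output is a subset of the threshold-only output at the same p
  for (p_lab in c("p_0.001", "p_0.5")) {
    expect_true(all(res[["r2_0.2"]][[p_lab]]$variant_id %in%
                      res[["r2_1"]][[p_lab]]$variant_id))
  }

  # two perfectly correlated variants: the smaller p-value survives
  set.seed(3)
  x <- rbinom(400, 2, 0.3)
  panel2 <- reference_panel(cbind(x, x), data.frame(
    variant_id = c("a", "b"), chrom = "1", pos = c(1000, 2000),
    a1 = "A", a2 = "G"))
  st2 <- summary_stats(c("a", "b"), "1", c(1000, 2000), "A", "G",
                       beta = c(0.2, 0.3), se = c(0.1, 0.1),
                       eaf = 0.3, n = 400)
  res2 <- baseline_threshold_and_clump(st2, panel2, p_thresholds = 1,
                                       r2_clump = 0.8)
  expect_identical(res2[["r2_0.8"]][["p_1"]]$variant_id, "b")
})

test_that("clumping matches a brute-force reference implementation", {
  d <- small_dataset(P = 60, block_size = 20, n_train = 1200, n_ref = 400,
                     rho_within = 0.7, rho_cross = 0.3, n_causal = 6,
                     h2 = 0.4, seed = 77)
  pvals <- 2 * pnorm(-abs(d$stats$beta / d$stats$se))
  g <- d$panel$genotypes
  chrom <- d$stats$chrom; pos <- d$stats$pos

  brute_clump <- function(r2_thr, window) {
    removed <- logical(length(pvals))
    surv <- integer(0)
    remaining <- order(pvals)
    while (length(remaining)) {
      i <- remaining[1]
      surv <- c(surv, i)
      drop <- vapply(remaining[-1], function(j) {
        chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window &&
          cor(g[, i], g[, j])^2 > r2_thr
      }, TRUE)
      remaining <- remaining[-1][!drop]
    }
    sort(surv)
  }
  for (r2 in c(0.2, 0.5, 0.8)) {
    res <- baseline_threshold_and_clump(d$stats, d$panel, p_thresholds = 1,
                                        r2_clump = r2, window_kb = 250)
    mine <- sort(match(res[[sprintf("r2_%g", r2)]][["p_1"]]$variant_id,
                       d$stats$variant_id))
    expect_identical(mine, brute_clump(r2, 250 * 1000))
  }
})
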