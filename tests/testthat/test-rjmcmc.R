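make_block <- function(P = 8, seed = 13, ...) {
  d <- small_dataset(P = P, block_size = P, n_ref = 600,
                     n_causal = min(3, P), seed = seed, ...)
  build_block_data(d$stats, d$panel)
}

test_that("model_state enforces its invariants", {
  expect_error(model_state(c(TRUE, FALSE), c(0.1, 0.2), 0.3, 1), "beta")
  expect_error(model_state(c(TRUE, FALSE), c(0.1, 0), 3, 1), "support")
  expect_error(model_state(c(TRUE, FALSE), c(0.1, 0), 0.3, -1), "sigma2")
  s <- model_state(c(TRUE, FALSE), c(0.1, 0), 0.3, 1)
  expect_s3_class(s, "model_state")
})

test_that("delete from a single-variant model proposes the null model", {
  bd <- make_block(4)
  cfg <- sampler_config(n_iter = 100, seed = 1,
                        move_probs = c(add = 0, delete = 1, swap = 0,
                                       beta = 0, sigma_beta = 0,
                                       sigma2 = 0))
  st <- model_state(c(TRUE, FALSE, FALSE, FALSE), c(0.4, 0, 0, 0), 0.3, 1)
  set.seed(2)
  pr <- propose(st, bd, cfg)
  expect_equal(pr$move, "delete")
  expect_equal(sum(pr$proposal$gamma), 0)
  expect_true(all(pr$proposal$beta == 0))
})

test_that("add-then-delete returns the original state with q-ratios summing to zero", {
  bd <- make_block(2)
  cfg <- sampler_config(n_iter = 100, seed = 1,
                        move_probs = c(add = 0.5, delete = 0.5, swap = 0,
                                       beta = 0, sigma_beta = 0,
                                       sigma2 = 0))
  st0 <- model_state(c(FALSE, FALSE), c(0, 0), 0.3, 1)
  set.seed(7)
  for (trial in 1:20) {
    pr1 <- propose(st0, bd, cfg)       # only add is valid at the null
    expect_equal(pr1$move, "add")
    j <- which(pr1$proposal$gamma)
    repeat {
      pr2 <- propose(pr1$proposal, bd, cfg)
      if (pr2$move == "delete" && !pr2$proposal$gamma[j]) break
    }
    expect_equal(pr2$proposal$gamma, st0$gamma)
    expect_equal(pr2$proposal$beta, st0$beta)
    expect_equal(pr1$log_q_ratio + pr2$log_q_ratio, 0, tolerance = 1e-12)
  }
})

test_that("move frequencies follow the validity-conditioned probabilities", {
  bd <- make_block(10)
  cfg <- sampler_config(n_iter = 100, seed = 1)
  st <- model_state(c(rep(TRUE, 3), rep(FALSE, 7)),
                    c(rnorm(3, 0, 0.2), rep(0, 7)), 0.3, 1)
  set.seed(5)
  n_draw <- 40000
  moves <- vapply(seq_len(n_draw), function(i) propose(st, bd, cfg)$move, "")
  tab <- table(factor(moves, levels = names(cfg$move_probs)))
  # all moves valid at 0 < k < p, so expected frequencies = move_probs
  for (m in names(cfg$move_probs)) {
    p0 <- cfg$move_probs[[m]]
    se <- sqrt(p0 * (1 - p0) / n_draw)
    expect_lt(abs(tab[[m]] / n_draw - p0), 3.5 * se)
  }
})

test_that("MH ratio is zero for an identical proposal and analytic for add", {
  bd <- flat_block(5)   # z = 0, L = I: the likelihood depends only on beta
  pr <- prior_config(lambda = 0.5)
  st <- model_state(rep(FALSE, 5), rep(0, 5), 0.3, 1)
  expect_equal(mh_log_ratio(st, st, bd, pr, 0), 0)

  cfg <- sampler_config(n_iter = 100, prior = pr, fix_sigma2 = 1,
                        move_probs = c(add = 0.4, delete = 0.4, swap = 0,
                                       beta = 0.2, sigma_beta = 0,
                                       sigma2 = 0))
  set.seed(3)
  prop <- propose(st, bd, cfg)
  expect_equal(prop$move, "add")
  b <- prop$proposal$beta[prop$proposal$gamma]
  mh <- mh_log_ratio(st, prop$proposal, bd, pr, prop$log_q_ratio)
  # likelihood term -b^2/2, beta-binomial prior ratio, and the resampled
  # move-probability bookkeeping; the effect prior cancels the q density
  mv <- cfg$move_probs
  norm0 <- mv[["add"]]                 # only add valid at the null model
  norm1 <- mv[["add"]] + mv[["delete"]] + mv[["beta"]]
  expected <- -b^2 / 2 +
    log_model_prior(1, 5, 0.5) - log_model_prior(0, 5, 0.5) +
    log(mv[["delete"]] / norm1) - log(1) -
    (log(mv[["add"]] / norm0) - log(5))
  expect_equal(mh, expected, tolerance = 1e-10)
})

test_that("the sampler is deterministic given its seed", {
  bd <- make_block(6, seed = 17)
  cfg <- sampler_config(n_iter = 4000, seed = 99,
                        prior = prior_config(lambda = 0.1))
  f1 <- run_block_sampler(bd, cfg)
  f2 <- run_block_sampler(bd, cfg)
  expect_identical(f1$posterior_mean_beta, f2$posterior_mean_beta)
  expect_identical(f1$diagnostics$accepted, f2$diagnostics$accepted)
  f3 <- run_block_sampler(bd, sampler_config(n_iter = 4000, seed = 100,
                                             prior = prior_config(0.1)))
  expect_false(identical(f1$posterior_mean_beta, f3$posterior_mean_beta))
})

test_that("null data yields shrunken weights relative to real signal", {
  d_alt <- small_dataset(P = 10, block_size = 10, n_train = 2000,
                         n_ref = 800, n_causal = 2, h2 = 0.4, seed = 23)
  d_null <- small_dataset(P = 10, block_size = 10, n_train = 2000,
                          n_ref = 800, n_causal = 2, h2 = 0, seed = 23)
  cfg <- sampler_config(n_iter = 20000, seed = 5,
                        prior = prior_config(lambda = 0.01))
  f_alt <- run_block_sampler(build_block_data(d_alt$stats, d_alt$panel), cfg)
  f_null <- run_block_sampler(build_block_data(d_null$stats, d_null$panel),
                              cfg)
  scale_alt <- max(abs(f_alt$posterior_mean_beta))
  expect_gt(scale_alt, 0)
  expect_lt(max(abs(f_null$posterior_mean_beta)), 0.05 * scale_alt)
})

test_that("posterior summaries respect parameter supports", {
  bd <- make_block(6, seed = 19)
  cfg <- sampler_config(n_iter = 10000, seed = 1)
  f <- run_block_sampler(bd, cfg)
  expect_gte(f$diagnostics$sigma_beta_mean, 0.05)
  expect_lte(f$diagnostics$sigma_beta_mean, 2)
  expect_gt(f$diagnostics$sigma2_mean, 0)
  expect_equal(sum(f$diagnostics$size_counts), f$diagnostics$n_kept)
  expect_equal(f$posterior_mean_model_size, sum(f$pip), tolerance = 1e-10)
})

test_that("posterior mean weights are invariant under variant relabeling", {
  d <- small_dataset(P = 8, block_size = 8, n_train = 2000, n_ref = 800,
                     n_causal = 2, h2 = 0.4, seed = 29)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  bd <- build_block_data(d$stats, d$panel)
  st_p <- d$stats[perm, , drop = FALSE]
  class(st_p) <- c("summary_stats", "data.frame")
  bd_p <- build_block_data(st_p, panel_perm <- reference_panel(
    d$panel$genotypes[, perm], d$panel$variants[perm, , drop = FALSE]))
  cfg <- sampler_config(n_iter = 60000, seed = 7,
                        prior = prior_config(lambda = 0.1))
  f <- run_block_sampler(bd, cfg)
  f_p <- run_block_sampler(bd_p, sampler_config(n_iter = 60000, seed = 8,
                                                prior = prior_config(0.1)))
  back <- f_p$posterior_mean_beta[order(perm)]
  expect_lt(max(abs(f$posterior_mean_beta - back)),
            0.03 * max(abs(f$posterior_mean_beta)) + 0.003)
})

test_that("exact enumeration normalizes and prefers the null on null data", {
  bd <- flat_block(1, z = 0.1)
  pr <- prior_config(lambda = 1)
  en <- enumerate_posterior(bd, pr, sigma_beta = 0.3, sigma2 = 1)
  expect_equal(sum(en$models$prob), 1, tolerance = 1e-12)
  expect_equal(en$models$model[which.max(en$models$prob)], "")
  bd8 <- make_block(8, seed = 37)
  en8 <- enumerate_posterior(bd8, pr, 0.3, 1)
  expect_equal(sum(en8$models$prob), 1, tolerance = 1e-10)
  expect_length(en8$pip, 8)
  expect_error(enumerate_posterior(make_block(16), pr, 0.3, 1), "p <= 15")
})

test_that("conjugate marginal likelihood agrees with direct quadrature", {
  bd <- make_block(4, seed = 41)
  sb <- 0.25; s2 <- 0.8
  z <- as.numeric(bd$z); L <- bd$L
  # model {2}: integrate the effect out numerically; the integrand is a
  # narrow peak, so locate it and stabilize the exponent first
  loglik <- function(bb)
    sum(dnorm(z, L[, 2] * bb, sqrt(s2), log = TRUE)) +
      dnorm(bb, 0, sb, log = TRUE)
  grid <- seq(-2, 2, length.out = 4001)
  lg <- vapply(grid, loglik, 0)
  M <- max(lg)
  bhat <- grid[which.max(lg)]
  lik <- function(b) vapply(b, function(bb) exp(loglik(bb) - M), 0)
  quad <- (integrate(lik, -2, bhat, rel.tol = 1e-9,
                     subdivisions = 1000L)$value +
           integrate(lik, bhat, 2, rel.tol = 1e-9,
                     subdivisions = 1000L)$value) * exp(M)
  Sig <- diag(s2, 4) + sb^2 * tcrossprod(L[, 2])
  R <- chol(Sig)
  closed <- exp(-0.5 * 4 * log(2 * pi) - sum(log(diag(R))) -
                  0.5 * sum(backsolve(R, z, transpose = TRUE)^2))
  expect_equal(closed / quad, 1, tolerance = 1e-6)
  # and enumerate_posterior uses exactly that marginal likelihood
  en <- enumerate_posterior(bd, prior_config(lambda = 0.5), sb, s2)
  row <- which(en$models$model == "2")
  expect_equal(en$models$log_post[row],
               log(closed) + log_model_prior(1, 4, 0.5), tolerance = 1e-8)
})
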