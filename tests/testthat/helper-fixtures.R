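# shared fixtures, all generated in code

options(blockprs.verbose = FALSE)

# small simulated dataset: panels + trait + training summaries, harmonized
small_dataset <- function(P = 30, n_train = 800, n_ref = 400, n_test = 200,
                          block_size = 10, rho_within = 0.4, rho_cross = 0,
                          n_causal = 3, h2 = 0.3, seed = 11, ...) {
  cfg <- sim_config(P = P, n_train = n_train, n_ref = n_ref,
                    n_test = n_test, block_size = block_size,
                    rho_within = rho_within, rho_cross = rho_cross,
                    n_causal = n_causal, h2 = h2, seed = seed, ...)
  sims <- simulate_genotypes(cfg)
  trait <- simulate_trait(sims$train, cfg)
  stats <- compute_univariate_summaries(sims$train, trait$y,
                                        binary = cfg$binary)
  h <- harmonize(stats, sims$ref)
  list(cfg = cfg, sims = sims, trait = trait, stats = h$stats,
       panel = h$panel)
}

# a block_data object with a fully controlled likelihood (identity L)
flat_block <- function(p, z = rep(0, p)) {
  structure(list(xty = z, xtx = diag(p), L = diag(p), z = z, n = 1000,
                 variant_ids = paste0("v", seq_len(p)), p = p),
            class = "block_data")
}

# beta-binomial prior mass over model size k (sums to 1 over k = 0..P)
size_prior <- function(P, lambda) {
  k <- 0:P
  exp(lchoose(P, k) + log_model_prior(k, P, lambda))
}
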