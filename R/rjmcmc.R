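#' Sampler state: variant selection and parameters
#'
#' @param gamma logical/0-1 inclusion vector of length `p`.
#' @param beta effect vector of length `p`; must be zero wherever
#'   `gamma == 0`.
#' @param sigma_beta effect-prior standard deviation.
#' @param sigma2 residual variance, > 0.
#' @param prior a [prior_config()] used to validate `sigma_beta` support.
#' @return an object of class `model_state`.
#' @export
model_state <- function(gamma, beta, sigma_beta, sigma2,
                        prior = prior_config()) {
  gamma <- as.logical(gamma)
  if (length(gamma) != length(beta))
    stop("gamma and beta lengths differ", call. = FALSE)
  if (any(beta[!gamma] != 0))
    stop("beta must be 0 wherever gamma is 0", call. = FALSE)
  if (sigma_beta < prior$sigma_beta_min || sigma_beta > prior$sigma_beta_max)
    stop("sigma_beta outside prior support", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  structure(list(gamma = gamma, beta = as.numeric(beta),
                 sigma_beta = sigma_beta, sigma2 = sigma2),
            class = "model_state")
}

#' Reversible-jump sampler configuration
#'
#' @param n_iter total iterations (200,000 by default, matching the Step-1
#'   analyses the method was developed with).
#' @param burn_in_frac fraction of iterations discarded as burn-in.
#' @param seed RNG seed; runs are bitwise reproducible given the seed.
#' @param move_probs probabilities of the add / delete / swap /
#'   effect-update / sigma_beta / sigma2 moves. At states where a move is
#'   impossible (e.g. delete at the null model) the move is resampled among
#'   the valid ones; the per-state renormalization enters the proposal
#'   ratio so detailed balance is exact.
#' @param prior a [prior_config()].
#' @param fix_sigma_beta,fix_sigma2 optionally fix these parameters (their
#'   update moves are then disabled); used for oracle comparisons against
#'   exhaustive enumeration.
#' @param thin recording interval for the model-size trace.
#' @param adapt adapt random-walk step sizes during burn-in only (target
#'   acceptance 0.25-0.45), frozen afterwards.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 200000, burn_in_frac = 0.5, seed = 1,
                           move_probs = c(add = 0.2, delete = 0.2,
                                          swap = 0.1, beta = 0.3,
                                          sigma_beta = 0.1, sigma2 = 0.1),
                           prior = prior_config(), fix_sigma_beta = NULL,
                           fix_sigma2 = NULL, thin = 100, adapt = TRUE) {
  nm <- c("add", "delete", "swap", "beta", "sigma_beta", "sigma2")
  if (!all(nm %in% names(move_probs)))
    stop("move_probs must be named ", paste(nm, collapse = ", "),
         call. = FALSE)
  move_probs <- move_probs[nm]
  if (any(move_probs < 0) || sum(move_probs) <= 0)
    stop("move_probs must be non-negative and not all zero", call. = FALSE)
  move_probs <- move_probs / sum(move_probs)
  if (burn_in_frac <= 0 || burn_in_frac >= 1)
    stop("burn_in_frac must be in (0, 1)", call. = FALSE)
  if (n_iter * (1 - burn_in_frac) < 1)
    stop("n_iter must exceed the burn-in", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in_frac = burn_in_frac, seed = as.integer(seed),
                 move_probs = move_probs, prior = prior,
                 fix_sigma_beta = fix_sigma_beta, fix_sigma2 = fix_sigma2,
                 thin = as.integer(thin), adapt = isTRUE(adapt)),
            class = "sampler_config")
}

# which moves are available at model size k (fixed parameters disable moves)
move_validity <- function(k, p, mv) {
  c(add = k < p, delete = k > 0, swap = k > 0 && k < p, beta = k > 0,
    sigma_beta = mv[["sigma_beta"]] > 0, sigma2 = mv[["sigma2"]] > 0)
}

#' Propose a reversible-jump move
#'
#' Draws one of the add / delete / swap / effect random-walk / sigma_beta
#' random-walk / log-sigma2 random-walk moves, conditioned on validity at
#' the current state, and returns the proposal together with the log
#' proposal-density ratio `log q(current | proposal) - log q(proposal |
#' current)` needed by the Metropolis-Hastings ratio. New effects in add
#' and swap moves are drawn from their `N(0, sigma_beta^2)` prior, so the
#' effect-prior terms cancel in the full ratio.
#'
#' Uses the current RNG stream; seed it with `set.seed()` for
#' reproducibility.
#'
#' @param state a [model_state()].
#' @param block a [build_block_data()] result (only dimensions are used).
#' @param config a [sampler_config()].
#' @return `list(proposal = model_state, log_q_ratio = , move = )`.
#' @export
propose <- function(state, block, config) {
  p <- block$p
  mv <- config$move_probs
  if (!is.null(config$fix_sigma_beta)) mv[["sigma_beta"]] <- 0
  if (!is.null(config$fix_sigma2)) mv[["sigma2"]] <- 0
  k <- sum(state$gamma)
  valid <- move_validity(k, p, mv)
  norm_cur <- sum(mv[valid])
  move <- sample(names(mv), 1, prob = ifelse(valid, mv, 0))
  prior <- config$prior
  sb <- state$sigma_beta
  new <- state
  lqr <- 0

  norm_at <- function(k2) sum(mv[move_validity(k2, p, mv)])

  if (move == "add") {
    excl <- which(!state$gamma)
    j <- excl[sample.int(length(excl), 1)]
    b <- rnorm(1, 0, sb)
    new$gamma[j] <- TRUE; new$beta[j] <- b
    lqr <- log(mv[["delete"]] / norm_at(k + 1)) - log(k + 1) -
      (log(mv[["add"]] / norm_cur) - log(p - k) + dnorm(b, 0, sb, log = TRUE))
  } else if (move == "delete") {
    incl <- which(state$gamma)
    j <- incl[sample.int(length(incl), 1)]
    b <- state$beta[j]
    new$gamma[j] <- FALSE; new$beta[j] <- 0
    lqr <- log(mv[["add"]] / norm_at(k - 1)) - log(p - k + 1) +
      dnorm(b, 0, sb, log = TRUE) - (log(mv[["delete"]] / norm_cur) - log(k))
  } else if (move == "swap") {
    incl <- which(state$gamma); excl <- which(!state$gamma)
    j <- incl[sample.int(length(incl), 1)]
    l <- excl[sample.int(length(excl), 1)]
    b_new <- rnorm(1, 0, sb)
    new$gamma[j] <- FALSE; new$beta[j] <- 0
    new$gamma[l] <- TRUE; new$beta[l] <- b_new
    lqr <- dnorm(state$beta[j], 0, sb, log = TRUE) -
      dnorm(b_new, 0, sb, log = TRUE)
  } else if (move == "beta") {
    incl <- which(state$gamma)
    j <- incl[sample.int(length(incl), 1)]
    new$beta[j] <- state$beta[j] + 0.2 * sb * rnorm(1)
    lqr <- 0
  } else if (move == "sigma_beta") {
    new$sigma_beta <- reflect_into(sb + 0.2 * rnorm(1),
                                   prior$sigma_beta_min,
                                   prior$sigma_beta_max)
    lqr <- 0
  } else {  # sigma2: symmetric random walk on log sigma2
    new$sigma2 <- exp(log(state$sigma2) + 0.5 * rnorm(1))
    lqr <- log(new$sigma2) - log(state$sigma2)
  }
  list(proposal = new, log_q_ratio = lqr, move = move)
}

#' Metropolis-Hastings log acceptance ratio
#'
#' `log P(D | proposal) + log P(theta* | gamma*) + log P(gamma*)` minus the
#' same terms for the current state, plus the supplied log proposal-density
#' ratio. The parameter prior comprises the `N(0, sigma_beta^2)` densities
#' of the selected effects, the uniform prior on `sigma_beta`, and the
#' inverse-gamma prior on `sigma2`.
#'
#' @param current,proposal [model_state()] objects.
#' @param block a [build_block_data()] result.
#' @param prior a [prior_config()].
#' @param log_q_ratio log proposal ratio from [propose()].
#' @return scalar log acceptance ratio (accept with probability
#'   `min(1, exp(value))`).
#' @export
mh_log_ratio <- function(current, proposal, block, prior, log_q_ratio = 0) {
  lp <- function(s) {
    k <- sum(s$gamma)
    ll <- log_likelihood(s, block)
    ltheta <- sum(dnorm(s$beta[s$gamma], 0, s$sigma_beta, log = TRUE)) +
      stats::dunif(s$sigma_beta, prior$sigma_beta_min, prior$sigma_beta_max,
                   log = TRUE) +
      ldinvgamma(s$sigma2, prior$ig_a, prior$ig_b)
    lgam <- log_model_prior(k, block$p, prior$lambda)
    ll + ltheta + lgam
  }
  lp(proposal) - lp(current) + log_q_ratio
}

#' Fit one block by reversible-jump MCMC
#'
#' Samples the posterior over variant selections and effects for a single
#' block and returns Bayesian-model-averaged weights: the posterior mean of
#' each effect over all post-burn-in iterations, counting zeros from
#' iterations in which the variant was excluded. The sampler is a
#' fixed-scan Metropolis-Hastings kernel over the moves of [propose()],
#' with the residual variance updated by its conjugate inverse-gamma Gibbs
#' step and the likelihood evaluated incrementally (each move touches at
#' most two coordinates of `beta`). Deterministic given `config$seed`.
#'
#' @param block a [build_block_data()] result.
#' @param config a [sampler_config()].
#' @return a list of class `block_fit` with `posterior_mean_beta`, `pip`
#'   (posterior inclusion probabilities), `posterior_mean_model_size`,
#'   `variant_ids`, and `diagnostics` (per-move proposal and acceptance
#'   counts, model-size counts and thinned trace, posterior means of
#'   `sigma2` and `sigma_beta`, final step sizes).
#' @export
run_block_sampler <- function(block, config) {
  stopifnot(inherits(block, "block_data"), inherits(config, "sampler_config"))
  p <- block$p
  prior <- config$prior
  L <- block$L
  z <- as.numeric(block$z)
  cn2 <- colSums(L^2)
  mv <- config$move_probs
  if (!is.null(config$fix_sigma_beta)) mv[["sigma_beta"]] <- 0
  if (!is.null(config$fix_sigma2)) mv[["sigma2"]] <- 0
  if (sum(mv) <= 0) stop("no moves enabled", call. = FALSE)
  mv <- mv / sum(mv)
  m_add <- mv[["add"]]; m_del <- mv[["delete"]]; m_swap <- mv[["swap"]]
  m_beta <- mv[["beta"]]; m_sb <- mv[["sigma_beta"]]; m_s2 <- mv[["sigma2"]]

  n_iter <- config$n_iter
  burn <- floor(n_iter * config$burn_in_frac)
  lp <- log_model_prior(0:p, p, prior$lambda)
  norm_k <- vapply(0:p, function(k) sum(mv[move_validity(k, p, mv)]), 0)

  set.seed(config$seed)
  gam <- logical(p); beta <- numeric(p); k <- 0L
  sb <- config$fix_sigma_beta %||%
    sqrt(prior$sigma_beta_min * prior$sigma_beta_max)
  s2 <- config$fix_sigma2 %||% 1
  sb_lo <- prior$sigma_beta_min; sb_hi <- prior$sigma_beta_max
  r <- z; rss <- sum(r * r); sumb2 <- 0
  step_b <- 0.2; step_sb <- 0.2

  sum_beta <- numeric(p); sum_gam <- numeric(p)
  sum_k <- 0; sum_s2 <- 0; sum_sb <- 0; n_keep <- 0L
  size_counts <- integer(p + 1)
  k_trace <- integer(n_iter %/% config$thin); i_trace <- 0L
  mvnames <- c("add", "delete", "swap", "beta", "sigma_beta", "sigma2")
  prop_n <- acc_n <- setNames(integer(6), mvnames)
  win_prop <- win_acc <- c(beta = 0L, sigma_beta = 0L)

  for (i in seq_len(n_iter)) {
    u <- runif(1) * norm_k[k + 1L]
    # walk the valid moves in fixed order
    acc_add <- if (k < p) m_add else 0
    acc_del <- acc_add + (if (k > 0L) m_del else 0)
    acc_swap <- acc_del + (if (k > 0L && k < p) m_swap else 0)
    acc_bet <- acc_swap + (if (k > 0L) m_beta else 0)
    acc_sbm <- acc_bet + m_sb

    if (u < acc_add) {                                   # ---- add
      prop_n[[1L]] <- prop_n[[1L]] + 1L
      n_excl <- p - k
      j <- which(!gam)[sample.int(n_excl, 1L)]
      b <- rnorm(1, 0, sb)
      Lj <- L[, j]
      dot <- sum(Lj * r)
      rss_new <- rss - 2 * b * dot + b * b * cn2[j]
      la <- (rss - rss_new) / (2 * s2) + lp[k + 2L] - lp[k + 1L] +
        log(m_del / norm_k[k + 2L]) - log(k + 1) -
        log(m_add / norm_k[k + 1L]) + log(n_excl)
      if (log(runif(1)) < la) {
        acc_n[[1L]] <- acc_n[[1L]] + 1L
        gam[j] <- TRUE; beta[j] <- b
        r <- r - b * Lj; rss <- rss_new
        sumb2 <- sumb2 + b * b; k <- k + 1L
      }
    } else if (u < acc_del) {                            # ---- delete
      prop_n[[2L]] <- prop_n[[2L]] + 1L
      j <- which(gam)[sample.int(k, 1L)]
      b <- beta[j]
      Lj <- L[, j]
      dot <- sum(Lj * r)
      rss_new <- rss + 2 * b * dot + b * b * cn2[j]
      la <- (rss - rss_new) / (2 * s2) + lp[k] - lp[k + 1L] +
        log(m_add / norm_k[k]) - log(p - k + 1) -
        log(m_del / norm_k[k + 1L]) + log(k)
      if (log(runif(1)) < la) {
        acc_n[[2L]] <- acc_n[[2L]] + 1L
        gam[j] <- FALSE; beta[j] <- 0
        r <- r + b * Lj; rss <- rss_new
        sumb2 <- sumb2 - b * b; k <- k - 1L
      }
    } else if (u < acc_swap) {                           # ---- swap
      prop_n[[3L]] <- prop_n[[3L]] + 1L
      j <- which(gam)[sample.int(k, 1L)]
      l <- which(!gam)[sample.int(p - k, 1L)]
      b_old <- beta[j]
      b_new <- rnorm(1, 0, sb)
      r_new <- r + b_old * L[, j] - b_new * L[, l]
      rss_new <- sum(r_new * r_new)
      la <- (rss - rss_new) / (2 * s2)
      if (log(runif(1)) < la) {
        acc_n[[3L]] <- acc_n[[3L]] + 1L
        gam[j] <- FALSE; beta[j] <- 0
        gam[l] <- TRUE; beta[l] <- b_new
        r <- r_new; rss <- rss_new
        sumb2 <- sumb2 + b_new * b_new - b_old * b_old
      }
    } else if (u < acc_bet) {                            # ---- beta update
      prop_n[[4L]] <- prop_n[[4L]] + 1L
      win_prop[["beta"]] <- win_prop[["beta"]] + 1L
      j <- which(gam)[sample.int(k, 1L)]
      b0 <- beta[j]
      b1 <- b0 + step_b * sb * rnorm(1)
      d <- b1 - b0
      Lj <- L[, j]
      dot <- sum(Lj * r)
      rss_new <- rss - 2 * d * dot + d * d * cn2[j]
      la <- (rss - rss_new) / (2 * s2) + (b0 * b0 - b1 * b1) / (2 * sb * sb)
      if (log(runif(1)) < la) {
        acc_n[[4L]] <- acc_n[[4L]] + 1L
        win_acc[["beta"]] <- win_acc[["beta"]] + 1L
        beta[j] <- b1
        r <- r - d * Lj; rss <- rss_new
        sumb2 <- sumb2 + b1 * b1 - b0 * b0
      }
    } else if (u < acc_sbm) {                            # ---- sigma_beta
      prop_n[[5L]] <- prop_n[[5L]] + 1L
      win_prop[["sigma_beta"]] <- win_prop[["sigma_beta"]] + 1L
      sb1 <- reflect_into(sb + step_sb * rnorm(1), sb_lo, sb_hi)
      la <- -k * (log(sb1) - log(sb)) -
        0.5 * sumb2 * (1 / (sb1 * sb1) - 1 / (sb * sb))
      if (log(runif(1)) < la) {
        acc_n[[5L]] <- acc_n[[5L]] + 1L
        win_acc[["sigma_beta"]] <- win_acc[["sigma_beta"]] + 1L
        sb <- sb1
      }
    } else {                                             # ---- sigma2 Gibbs
      prop_n[[6L]] <- prop_n[[6L]] + 1L
      acc_n[[6L]] <- acc_n[[6L]] + 1L
      s2 <- 1 / rgamma(1, shape = prior$ig_a + p / 2,
                       rate = prior$ig_b + rss / 2)
    }

    # step-size adaptation, burn-in only
    if (config$adapt && i <= burn) {
      if (win_prop[["beta"]] >= 50L) {
        rate <- win_acc[["beta"]] / win_prop[["beta"]]
        if (rate > 0.45) step_b <- step_b * 1.25
        else if (rate < 0.25) step_b <- step_b / 1.25
        win_prop[["beta"]] <- win_acc[["beta"]] <- 0L
      }
      if (win_prop[["sigma_beta"]] >= 50L) {
        rate <- win_acc[["sigma_beta"]] / win_prop[["sigma_beta"]]
        if (rate > 0.45) step_sb <- min(step_sb * 1.25, sb_hi - sb_lo)
        else if (rate < 0.25) step_sb <- step_sb / 1.25
        win_prop[["sigma_beta"]] <- win_acc[["sigma_beta"]] <- 0L
      }
    }

    # guard against incremental round-off drift on long runs
    if (i %% 20000L == 0L) {
      r <- z - as.vector(L %*% beta)
      rss <- sum(r * r)
      sumb2 <- sum(beta[gam]^2)
    }

    if (i > burn) {
      n_keep <- n_keep + 1L
      sum_beta <- sum_beta + beta
      sum_gam <- sum_gam + gam
      sum_k <- sum_k + k
      sum_s2 <- sum_s2 + s2
      sum_sb <- sum_sb + sb
      size_counts[k + 1L] <- size_counts[k + 1L] + 1L
    }
    if (i %% config$thin == 0L) {
      i_trace <- i_trace + 1L
      k_trace[i_trace] <- k
    }
  }

  acc_rate <- ifelse(prop_n > 0, acc_n / prop_n, NA_real_)
  if (all(acc_n[1:4] == 0) && sum(prop_n[1:4]) > 0)
    warning("chain never accepted a model or effect move; ",
            "posterior summaries are unreliable", call. = FALSE)

  structure(list(
    posterior_mean_beta = sum_beta / n_keep,
    pip = sum_gam / n_keep,
    posterior_mean_model_size = sum_k / n_keep,
    variant_ids = block$variant_ids,
    diagnostics = list(
      proposals = prop_n, accepted = acc_n, acceptance = acc_rate,
      size_counts = size_counts, k_trace = k_trace[seq_len(i_trace)],
      sigma2_mean = sum_s2 / n_keep, sigma_beta_mean = sum_sb / n_keep,
      step_beta = step_b, step_sigma_beta = step_sb, n_kept = n_keep)),
    class = "block_fit")
}

#' Exact posterior over all selections of a small block
#'
#' With `sigma_beta` and `sigma2` fixed, the selected effects are Gaussian
#' and integrate out analytically: under selection `S` the transformed data
#' are marginally `z ~ MVN(0, sigma2 I + sigma_beta^2 L_S L_S')`. Each of
#' the `2^p` selections is scored by this conjugate marginal likelihood
#' times the beta-binomial prior mass and the results normalized. Used as
#' the brute-force oracle for the MCMC sampler; limited to `p <= 15`.
#'
#' @param block a [build_block_data()] result with `p <= 15`.
#' @param prior a [prior_config()].
#' @param sigma_beta,sigma2 fixed values.
#' @return `list(models = data.frame(model, k, log_post, prob), pip = )`
#'   where `model` is a comma-separated index set and `pip` the per-variant
#'   posterior inclusion probabilities.
#' @export
enumerate_posterior <- function(block, prior, sigma_beta, sigma2) {
  p <- block$p
  if (p > 15) stop("enumeration limited to p <= 15 (got ", p, ")",
                   call. = FALSE)
  L <- block$L
  z <- as.numeric(block$z)
  lp <- log_model_prior(0:p, p, prior$lambda)
  n_mod <- 2^p
  log_post <- numeric(n_mod)
  ks <- integer(n_mod)
  labs <- character(n_mod)
  base_ll <- sum(dnorm(z, 0, sqrt(sigma2), log = TRUE))
  for (m in 0:(n_mod - 1)) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    k <- length(sel)
    ll <- if (k == 0) base_ll else {
      Ls <- L[, sel, drop = FALSE]
      ldmvnorm0(z, diag(sigma2, p) + sigma_beta^2 * tcrossprod(Ls))
    }
    log_post[m + 1] <- ll + lp[k + 1]
    ks[m + 1] <- k
    labs[m + 1] <- paste(sel, collapse = ",")
  }
  w <- exp(log_post - max(log_post))
  prob <- w / sum(w)
  pip <- vapply(seq_len(p), function(j) {
    has <- bitwAnd(0:(n_mod - 1), bitwShiftL(1L, j - 1)) > 0
    sum(prob[has])
  }, 0)
  list(models = data.frame(model = labs, k = ks, log_post = log_post,
                           prob = prob, stringsAsFactors = FALSE),
       pip = setNames(pip, block$variant_ids))
}
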