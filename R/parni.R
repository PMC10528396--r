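# The point-wise adaptive random neighbourhood informed (PARNI) proposal.
#
# Each iteration draws a flip-set k (position j enters with probability A_j
# if currently excluded, D_j if included), visits the flipped positions in a
# fresh uniform random order, and at each position chooses between keeping
# and flipping via a locally informed two-model kernel weighted by the
# Hastings balancing function of the posterior ratio times
# (zeta/(1-zeta))^{Hamming distance}. The reverse-path probability re-walks
# the same two-model pairs in reverse order, so it reuses the forward
# scores and costs no extra engine calls. A and D adapt through a convex
# combination of Schur-complement warm-start PIPs and the ergodic inclusion
# averages; zeta adapts by Robbins-Monro on the logit scale; the adaptive
# ALA initial guess eta-hat is the running mean of MAP linear predictors.

#' Hastings balancing function
#'
#' g_H(x) = min(1, x); satisfies the balancing identity g(x) = x g(1/x).
#'
#' @param x positive numeric vector.
#' @return numeric vector of the same length.
#' @export
balancing_gH <- function(x) {
  stopifnot(all(x > 0))
  pmin(1, x)
}

#' Hamming distance between two model indicators
#'
#' @param gamma1,gamma2 equal-length 0/1 (or logical) vectors.
#' @return integer count of differing positions.
#' @export
hamming <- function(gamma1, gamma2) {
  stopifnot(length(gamma1) == length(gamma2))
  sum(gamma1 != gamma2)
}

#' Draw a random flip-set k and visiting order
#'
#' k_j ~ Bernoulli(A_j) where gamma_j = 0 and Bernoulli(D_j) where
#' gamma_j = 1, independently; the active positions are returned in a
#' uniform random order.
#'
#' @param gamma_bin logical/0-1 vector of length p (current model).
#' @param A,D tuning vectors of length p.
#' @return list with logical `k`, `p_k` and the integer `order` vector.
#' @export
sample_k <- function(gamma_bin, A, D) {
  prob <- ifelse(gamma_bin, D, A)
  k <- stats::runif(length(prob)) < prob
  act <- which(k)
  ord <- if (length(act) > 1L) act[sample.int(length(act))] else act
  list(k = k, p_k = length(act), order = ord)
}

# log p(k | gamma) for a realised flip-set (companion density of sample_k).
log_k_density <- function(k, gamma_bin, A, D) {
  prob <- ifelse(gamma_bin, D, A)
  sum(log(ifelse(k, prob, 1 - prob)))
}

# Probability of flipping in a two-model informed kernel: the kernel puts
# weight 1 on staying and gH(exp(delta)) * zeta/(1-zeta) on flipping, where
# delta is the full log score difference (marginal likelihood + model prior
# + p(k|.) factor). Computed on the logit scale for stability.
flip_probability <- function(delta, log_zeta_odds) {
  stats::plogis(pmin(0, delta) + log_zeta_odds)
}

# Burn-in weight phi_l: above 1/2 before the burn-in boundary, exactly 1/2
# at l = N_b, decaying as (l - N_b)^{-1/2}/2 afterwards.
phi_weight <- function(l, n_burn) {
  if (l <= n_burn) 1 - 0.5 * (n_burn - l + 1)^(-0.5)
  else 0.5 * (l - n_burn)^(-0.5)
}

# Map composite PIP estimates to the A/D tuning vectors (clipped).
pips_to_AD <- function(pi_hat, epsilon) {
  A <- pmin(1, pi_hat / (1 - pi_hat))
  D <- pmin(1, (1 - pi_hat) / pi_hat)
  list(A = pmin(pmax(A, epsilon), 1 - epsilon),
       D = pmin(pmax(D, epsilon), 1 - epsilon))
}

# Toggle position j in a sorted index vector.
toggle_idx <- function(idx, j) {
  if (j %in% idx) idx[idx != j] else sort.int(c(idx, j))
}

# One point-wise informed walk. score_fn(idx) must return the proposal-side
# log score (log marginal likelihood + log model prior). Returns the
# proposed model, forward/reverse log proposal probabilities, the number of
# proposal-side model evaluations (2 per sub-neighbourhood), and the set of
# flipped positions.
pointwise_walk <- function(idx, gamma_bin, draw, A, D, zeta, score_fn) {
  lz <- log(zeta) - log1p(-zeta)
  logqf <- 0
  logqr <- 0
  n_eval <- 0L
  s_cur <- if (length(draw$order)) score_fn(idx) else 0
  gb <- gamma_bin
  for (j in draw$order) {
    idx_flip <- toggle_idx(idx, j)
    s_flip <- score_fn(idx_flip)
    n_eval <- n_eval + 2L
    dk <- if (gb[j]) log(A[j]) - log(D[j]) else log(D[j]) - log(A[j])
    delta <- s_flip - s_cur + dk
    pf <- flip_probability(delta, lz)
    if (stats::runif(1) < pf) {
      logqf <- logqf + log(pf)
      logqr <- logqr + log(flip_probability(-delta, lz))
      idx <- idx_flip
      gb[j] <- !gb[j]
      s_cur <- s_flip
    } else {
      logqf <- logqf + log1p(-pf)
      logqr <- logqr + log1p(-pf)
    }
  }
  list(idx = idx, gamma_bin = gb, log_q_forward = logqf,
       log_q_reverse = logqr, n_eval = n_eval,
       flipped = draw$order[gamma_bin[draw$order] != gb[draw$order]])
}

# log p(k|gamma') - log p(k|gamma) for the flipped positions (all other
# factors are identical between the two models).
log_k_ratio <- function(flipped, gamma_bin, A, D) {
  if (!length(flipped)) return(0)
  sum(ifelse(gamma_bin[flipped], log(A[flipped]) - log(D[flipped]),
             log(D[flipped]) - log(A[flipped])))
}

# The full PARNI chain. Both engines may be the same object (e.g. PARNI-DA
# uses one data-augmentation engine on both sides).
run_parni_chain <- function(data, prior, proposal_engine, acceptance_engine,
                            n_iter, burnin, epsilon = 0.001, zeta = 0.5,
                            adapt_zeta = TRUE, alpha_target = 0.234,
                            gamma0 = integer(0), learn_g = FALSE,
                            learn_k = FALSE, store_models = FALSE,
                            freeze_adaptation = FALSE,
                            pip_warm = NULL) {
  p <- data$p
  n <- data$n
  idx <- gamma_index(gamma0, p)
  gamma_bin <- logical(p)
  gamma_bin[idx] <- TRUE
  shape0 <- if (data$family == "weibull") data$shape else NULL
  if (is.null(pip_warm))
    pip_warm <- warm_start_pips(idx, data, prior, shape = shape0)
  pip_warm <- pmin(pmax(pip_warm, epsilon), 1 - epsilon)
  AD <- pips_to_AD(pip_warm, epsilon)
  A <- AD$A
  D <- AD$D
  same_engine <- identical(proposal_engine, acceptance_engine)
  eta_hat <- numeric(n)
  n_eta <- 0L
  incl_counts <- numeric(p)
  pip_sum <- numeric(p)
  n_keep <- 0L
  log_post <- numeric(n_iter)
  p_gamma_trace <- integer(n_iter)
  accept_flags <- logical(n_iter)
  p_k_trace <- integer(n_iter)
  eval_trace <- integer(n_iter)
  g_trace <- if (learn_g) numeric(n_iter) else NULL
  k_trace <- if (learn_k) numeric(n_iter) else NULL
  models <- if (store_models) vector("list", n_iter) else NULL
  hyper <- list(g = prior$g, log_k = log(if (is.null(shape0)) 1 else shape0),
                rw_scale = 0.5, aux = 1)
  lmp <- function(m) log_model_prior_size(m, prior, p)

  for (i in seq_len(n_iter)) {
    if (proposal_engine$method == "adaptive_ala")
      proposal_engine$set_eta(eta_hat)
    acceptance_engine$refresh(idx)
    draw <- sample_k(gamma_bin, A, D)
    score_fn <- function(m) proposal_engine$log_marglik(m) + lmp(length(m))
    walk <- pointwise_walk(idx, gamma_bin, draw, A, D, zeta, score_fn)
    p_k_trace[i] <- draw$p_k
    eval_trace[i] <- walk$n_eval
    if (length(walk$flipped) == 0L) {
      accepted <- TRUE
    } else {
      la_cur <- acceptance_engine$log_marglik(idx) + lmp(length(idx))
      la_prop <- acceptance_engine$log_marglik(walk$idx) +
        lmp(length(walk$idx))
      log_alpha <- la_prop - la_cur +
        log_k_ratio(walk$flipped, gamma_bin, A, D) +
        walk$log_q_reverse - walk$log_q_forward
      accepted <- log(stats::runif(1)) < log_alpha
    }
    if (accepted) {
      idx <- walk$idx
      gamma_bin <- walk$gamma_bin
    }
    accept_flags[i] <- accepted

    # -- adaptation (ergodic averages include the current sample) ---------
    if (!freeze_adaptation) {
      incl_counts <- incl_counts + gamma_bin
      pi_tilde <- incl_counts / i
      phi <- phi_weight(i, burnin)
      pi_hat <- phi * pip_warm + (1 - phi) * pi_tilde
      AD <- pips_to_AD(pmin(pmax(pi_hat, epsilon), 1 - epsilon), epsilon)
      A <- AD$A
      D <- AD$D
      if (adapt_zeta) {
        lgt <- log(zeta) - log1p(-zeta) +
          i^(-0.7) * (as.numeric(accepted) - alpha_target)
        zeta <- min(max(stats::plogis(lgt), epsilon), 1 - epsilon)
      }
      me <- acceptance_engine$mode_eta(idx)
      if (!is.null(me)) {
        n_eta <- n_eta + 1L
        eta_hat <- ((n_eta - 1) * eta_hat + me) / n_eta
      }
    }

    # -- hyper-parameter moves -------------------------------------------
    if (learn_g) {
      theta <- acceptance_engine$draw_theta(idx)
      beta <- if (length(theta) > data$q) theta[-seq_len(data$q)] else numeric(0)
      hyper <- update_g(hyper, beta)
      prior$g <- hyper$g
      proposal_engine$set_g(hyper$g)
      if (!same_engine) acceptance_engine$set_g(hyper$g)
      g_trace[i] <- hyper$g
    }
    if (learn_k) {
      hyper <- update_log_k(hyper, idx, acceptance_engine, prior, i)
      k_new <- exp(hyper$log_k)
      if (hyper$k_accepted) {
        proposal_engine$set_shape(k_new)
        if (!same_engine) acceptance_engine$set_shape(k_new)
      }
      k_trace[i] <- k_new
    }

    log_post[i] <- acceptance_engine$log_marglik(idx) + lmp(length(idx))
    p_gamma_trace[i] <- length(idx)
    if (i > burnin) {
      pip_sum <- pip_sum + gamma_bin
      n_keep <- n_keep + 1L
    }
    if (store_models) models[[i]] <- idx
  }

  list(pip = if (n_keep) pip_sum / n_keep else pip_sum,
       pip_ergodic = incl_counts / n_iter,
       pip_warm = pip_warm,
       log_post = log_post, p_gamma = p_gamma_trace,
       accepted = accept_flags, acceptance_rate = mean(accept_flags),
       p_k = p_k_trace, proposal_evals = eval_trace,
       zeta = zeta, A = A, D = D, eta_hat = eta_hat,
       g_trace = g_trace, k_trace = k_trace,
       models = models, final_model = idx, n_iter = n_iter, burnin = burnin)
}
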