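# Add-delete-swap baseline sampler. A move type is chosen uniformly among
# the feasible ones (delete and swap need a non-empty model, add and swap a
# non-full one); positions are uniform within type, and the MH correction
# accounts for the unequal neighbourhood counts of the forward and reverse
# moves.

feasible_moves <- function(pg, p) {
  mv <- character(0)
  if (pg < p) mv <- c(mv, "add")
  if (pg > 0) mv <- c(mv, "delete")
  if (pg > 0 && pg < p) mv <- c(mv, "swap")
  mv
}

# One add-delete-swap proposal + MH decision against the acceptance-side
# engine. Returns the new model and bookkeeping.
ads_step <- function(idx, data, prior, acc_engine) {
  p <- data$p
  pg <- length(idx)
  moves <- feasible_moves(pg, p)
  mv <- moves[sample.int(length(moves), 1L)]
  out_pool <- setdiff(seq_len(p), idx)
  if (mv == "add") {
    j <- out_pool[sample.int(length(out_pool), 1L)]
    idx_new <- sort.int(c(idx, j))
    log_q_f <- -log(length(moves)) - log(length(out_pool))
    log_q_r <- -log(length(feasible_moves(pg + 1L, p))) - log(pg + 1)
  } else if (mv == "delete") {
    j <- idx[sample.int(pg, 1L)]
    idx_new <- idx[idx != j]
    log_q_f <- -log(length(moves)) - log(pg)
    log_q_r <- -log(length(feasible_moves(pg - 1L, p))) - log(p - pg + 1)
  } else {
    j_in <- idx[sample.int(pg, 1L)]
    j_out <- out_pool[sample.int(length(out_pool), 1L)]
    idx_new <- sort.int(c(idx[idx != j_in], j_out))
    # swap keeps p_gamma, so the move-type and position counts cancel
    log_q_f <- 0
    log_q_r <- 0
  }
  la_cur <- acc_engine$log_marglik(idx) +
    log_model_prior_size(pg, prior, p)
  la_prop <- acc_engine$log_marglik(idx_new) +
    log_model_prior_size(length(idx_new), prior, p)
  log_alpha <- la_prop - la_cur + log_q_r - log_q_f
  accepted <- log(stats::runif(1)) < log_alpha
  list(idx = if (accepted) idx_new else idx, accepted = accepted,
       move = mv)
}

# Full add-delete-swap chain with the same trace layout as the PARNI runner.
run_ads_chain <- function(data, prior, acceptance_engine, n_iter, burnin,
                          gamma0 = integer(0), learn_g = FALSE,
                          learn_k = FALSE, store_models = FALSE) {
  p <- data$p
  idx <- gamma_index(gamma0, p)
  gamma_bin <- logical(p)
  gamma_bin[idx] <- TRUE
  incl_counts <- numeric(p)
  pip_sum <- numeric(p)
  n_keep <- 0L
  log_post <- numeric(n_iter)
  p_gamma_trace <- integer(n_iter)
  accept_flags <- logical(n_iter)
  g_trace <- if (learn_g) numeric(n_iter) else NULL
  k_trace <- if (learn_k) numeric(n_iter) else NULL
  models <- if (store_models) vector("list", n_iter) else NULL
  shape0 <- if (data$family == "weibull") data$shape else NULL
  hyper <- list(g = prior$g, log_k = log(if (is.null(shape0)) 1 else shape0),
                rw_scale = 0.5, aux = 1)

  for (i in seq_len(n_iter)) {
    acceptance_engine$refresh(idx)
    st <- ads_step(idx, data, prior, acceptance_engine)
    gamma_bin[idx] <- FALSE
    idx <- st$idx
    gamma_bin[idx] <- TRUE
    accept_flags[i] <- st$accepted
    incl_counts <- incl_counts + gamma_bin
    if (learn_g) {
      theta <- acceptance_engine$draw_theta(idx)
      beta <- if (length(theta) > data$q) theta[-seq_len(data$q)] else numeric(0)
      hyper <- update_g(hyper, beta)
      prior$g <- hyper$g
      acceptance_engine$set_g(hyper$g)
      g_trace[i] <- hyper$g
    }
    if (learn_k) {
      hyper <- update_log_k(hyper, idx, acceptance_engine, prior, i)
      if (hyper$k_accepted) acceptance_engine$set_shape(exp(hyper$log_k))
      k_trace[i] <- exp(hyper$log_k)
    }
    log_post[i] <- acceptance_engine$log_marglik(idx) +
      log_model_prior_size(length(idx), prior, p)
    p_gamma_trace[i] <- length(idx)
    if (i > burnin) {
      pip_sum <- pip_sum + gamma_bin
      n_keep <- n_keep + 1L
    }
    if (store_models) models[[i]] <- idx
  }

  list(pip = if (n_keep) pip_sum / n_keep else pip_sum,
       pip_ergodic = incl_counts / n_iter,
       log_post = log_post, p_gamma = p_gamma_trace,
       accepted = accept_flags, acceptance_rate = mean(accept_flags),
       g_trace = g_trace, k_trace = k_trace,
       models = models, final_model = idx, n_iter = n_iter, burnin = burnin)
}
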