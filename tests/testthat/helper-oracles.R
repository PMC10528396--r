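# Independent oracles used across the test files. These deliberately avoid
# the package's own computational routes.

# 1-D quadrature of the exact marginal likelihood for a single-coefficient
# model (q = 0): integrates p(y|beta) N(beta; 0, g) over beta on the log
# scale with a stabilising shift.
quadrature_marglik_1d <- function(j, data, prior, lower = -20, upper = 20) {
  xj <- data$x[, j]
  logf <- function(b) {
    vapply(b, function(bb) {
      eta <- bb * xj
      ll <- switch(data$family,
        logistic = sum(data$y * eta - log1p(exp(eta))),
        weibull = {
          k <- data$shape
          sum(data$event * (log(k) + k * eta + (k - 1) * data$log_time) -
                (data$time * exp(eta))^k)
        },
        stop("family not supported by this oracle"))
      ll + stats::dnorm(bb, 0, sqrt(prior$g), log = TRUE)
    }, numeric(1))
  }
  M <- stats::optimize(logf, c(lower, upper), maximum = TRUE)$objective
  val <- stats::integrate(function(b) exp(logf(b) - M), lower, upper,
                          rel.tol = 1e-10)$value
  M + log(val)
}

# Truncated-sum-of-gammas Polya-gamma sampler (independent of the Devroye
# route): PG(1, c) = (1/(2 pi^2)) sum_k g_k / ((k - 1/2)^2 + c^2/(4 pi^2)),
# g_k iid Exp(1), truncated at n_terms.
rpg1_series <- function(n, c = 0, n_terms = 500) {
  k <- seq_len(n_terms) - 0.5
  denom <- k^2 + c^2 / (4 * pi^2)
  vapply(seq_len(n), function(i) {
    sum(stats::rexp(n_terms) / denom) / (2 * pi^2)
  }, numeric(1))
}

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) 0/1 or numeric chain.
batch_se <- function(x, n_batch = 50) {
  m <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}

# A constant ("flat") marginal-likelihood engine stub matching the runner's
# interface: every model gets the same score, so the posterior over the
# lattice is driven by the model prior alone.
flat_engine <- function() {
  list(method = "flat", exact_target = TRUE, has_mode = FALSE,
       log_marglik = function(idx) 0,
       refresh = function(idx) invisible(NULL),
       set_eta = function(eta) invisible(NULL),
       mode_eta = function(idx) NULL,
       draw_theta = function(idx) numeric(0),
       set_g = function(g) invisible(NULL),
       set_shape = function(k) invisible(NULL),
       log_marglik_at_shape = function(idx, k) 0,
       clear_cache = function() invisible(NULL))
}

# Central finite differences of the log-likelihood in eta-space.
fd_score <- function(eta, data, h = 1e-5) {
  vapply(seq_along(eta), function(i) {
    ep <- eta; em <- eta
    ep[i] <- ep[i] + h
    em[i] <- em[i] - h
    (parni:::loglik_eta(ep, data) - parni:::loglik_eta(em, data)) / (2 * h)
  }, numeric(1))
}

fd_curvature <- function(eta, data, h = 1e-5) {
  n <- length(eta)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ep <- eta; em <- eta
    ep[i] <- ep[i] + h
    em[i] <- em[i] - h
    H[, i] <- -(fd_score(ep, data, h) - fd_score(em, data, h)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Posterior model probabilities of a stored model sequence on a small
# lattice, as a named table keyed by gamma_key.
model_freq <- function(models) {
  keys <- vapply(models, function(m) parni:::gamma_key(m), character(1))
  table(keys) / length(keys)
}
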