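# A uniform interface over the marginal-likelihood estimators, with the
# state each one carries across MCMC iterations: the LA/CPM mode cache, the
# CPM auxiliary normal block, the DA Polya-gamma variables, and the adaptive
# ALA linear-predictor guess. Engines memoise per-model log values for as
# long as their auxiliary state is unchanged; deterministic engines (la,
# ala) keep their cache for the whole run.

#' Construct a marginal-likelihood engine
#'
#' @param method one of `"la"`, `"ala"`, `"adaptive_ala"`, `"cpm"`, `"da"`
#'   (`"da"` is available for the logistic family only).
#' @param data a [bvs_data()] object.
#' @param prior a [bvs_prior()] object.
#' @param N CPM importance-sample count.
#' @param rho CPM auxiliary autocorrelation in [0, 1).
#' @return an object of class `"marglik_engine"`: a list of closures
#'   (`log_marglik`, `refresh`, `mode_eta`, ...) over shared mutable state.
#' @export
marglik_engine <- function(method = c("la", "ala", "adaptive_ala", "cpm",
                                      "da"),
                           data, prior, N = 32L, rho = 0.99) {
  method <- match.arg(method)
  if (method == "da" && data$family != "logistic")
    stop("Polya-gamma data augmentation is only available for the logistic family")
  ctx <- new.env(parent = emptyenv())
  ctx$data <- data
  ctx$prior <- prior
  ctx$shape <- if (data$family == "weibull") data$shape else NULL
  ctx$cache <- new.env(hash = TRUE, parent = emptyenv())
  ctx$mode_cache <- new.env(hash = TRUE, parent = emptyenv())
  ctx$eta_hat <- numeric(data$n)
  if (method == "da") ctx$omega <- rpg1(numeric(data$n))
  if (method == "cpm") {
    ctx$N <- as.integer(N)
    ctx$rho <- rho
    ctx$u <- matrix(stats::rnorm(ctx$N * (data$q + 8L)), nrow = ctx$N)
  }

  clear_cache <- function() ctx$cache <- new.env(hash = TRUE,
                                                parent = emptyenv())

  map_fit <- function(idx) {
    key <- gamma_key(idx)
    fit <- ctx$mode_cache[[key]]
    if (is.null(fit)) {
      fit <- map_estimate(idx, ctx$data, ctx$prior, shape = ctx$shape)
      ctx$mode_cache[[key]] <- fit
    }
    fit
  }

  ensure_u <- function(d) {
    if (d > ncol(ctx$u)) {
      extra <- matrix(stats::rnorm(ctx$N * (d - ncol(ctx$u))), nrow = ctx$N)
      ctx$u <- cbind(ctx$u, extra)
    }
    ctx$u
  }

  compute <- function(idx) {
    switch(method,
      la = log_marglik_la(idx, ctx$data, ctx$prior, shape = ctx$shape,
                          fit = map_fit(idx))$log_value,
      ala = log_marglik_ala(idx, ctx$data, ctx$prior,
                            shape = ctx$shape)$log_value,
      adaptive_ala = log_marglik_adaptive_ala(idx, ctx$data, ctx$prior,
                                              eta_hat = ctx$eta_hat,
                                              shape = ctx$shape)$log_value,
      cpm = {
        fit <- map_fit(idx)
        u <- ensure_u(length(fit$theta))
        log_marglik_cpm(idx, ctx$data, ctx$prior, u = u, shape = ctx$shape,
                        fit = fit)$log_value
      },
      da = pg_conditional_marglik(idx, ctx$omega, ctx$data, ctx$prior))
  }

  log_marglik <- function(idx) {
    key <- gamma_key(idx)
    val <- ctx$cache[[key]]
    if (is.null(val)) {
      val <- compute(idx)
      ctx$cache[[key]] <- val
    }
    val
  }

  # Per-iteration auxiliary refresh, called with the current model:
  #  - cpm: Crank-Nicolson move on the auxiliary block, accepted against the
  #    current model's estimate (a phi-invariant MH sub-step, so the
  #    extended chain stays exactly pseudo-marginal);
  #  - da: theta | gamma, omega then omega_i ~ PG(1, eta_i);
  #  - adaptive_ala and deterministic engines: nothing.
  refresh <- function(idx) {
    if (method == "cpm") {
      cur <- log_marglik(idx)
      u_old <- ctx$u
      ctx$u <- ctx$rho * u_old +
        sqrt(1 - ctx$rho^2) * matrix(stats::rnorm(length(u_old)),
                                     nrow = nrow(u_old))
      prop <- compute(idx)
      if (log(stats::runif(1)) < prop - cur) {
        clear_cache()
        ctx$cache[[gamma_key(idx)]] <- prop
      } else {
        ctx$u <- u_old
      }
    } else if (method == "da") {
      theta <- pg_draw_theta(idx, ctx$omega, ctx$data, ctx$prior)
      J <- build_design(idx, ctx$data)
      eta <- if (ncol(J)) drop(J %*% theta) else numeric(ctx$data$n)
      ctx$omega <- rpg1(eta)
      clear_cache()
    }
    invisible(NULL)
  }

  set_eta <- function(eta) {
    if (method == "adaptive_ala" && !identical(eta, ctx$eta_hat)) {
      ctx$eta_hat <- eta
      clear_cache()
    }
    invisible(NULL)
  }

  # MAP linear predictor of a model (engines that optimise store it).
  mode_eta <- function(idx) {
    if (!(method %in% c("la", "cpm"))) return(NULL)
    map_fit(idx)$eta
  }

  # Coefficient draw for hyper-parameter updates: exact conditional draw
  # under DA, the LA normal approximation otherwise.
  draw_theta <- function(idx) {
    if (method == "da")
      return(pg_draw_theta(idx, ctx$omega, ctx$data, ctx$prior))
    fit <- map_fit(idx)
    if (!length(fit$theta)) return(numeric(0))
    fit$theta + backsolve(fit$R, stats::rnorm(length(fit$theta)))
  }

  set_g <- function(g) {
    ctx$prior$g <- g
    ctx$mode_cache <- new.env(hash = TRUE, parent = emptyenv())
    clear_cache()
    invisible(NULL)
  }

  set_shape <- function(k) {
    ctx$shape <- k
    ctx$mode_cache <- new.env(hash = TRUE, parent = emptyenv())
    clear_cache()
    invisible(NULL)
  }

  # Uncached evaluation at an alternative Weibull shape (for k | gamma MH);
  # bypasses both caches so the stored state stays consistent.
  log_marglik_at_shape <- function(idx, k) {
    switch(method,
      la = log_marglik_la(idx, ctx$data, ctx$prior, shape = k)$log_value,
      ala = log_marglik_ala(idx, ctx$data, ctx$prior, shape = k)$log_value,
      adaptive_ala = log_marglik_adaptive_ala(idx, ctx$data, ctx$prior,
                                              eta_hat = ctx$eta_hat,
                                              shape = k)$log_value,
      cpm = {
        fit <- map_estimate(idx, ctx$data, ctx$prior, shape = k)
        u <- ensure_u(length(fit$theta))
        log_marglik_cpm(idx, ctx$data, ctx$prior, u = u, shape = k,
                        fit = fit)$log_value
      },
      stop("shape updates are not defined for engine '", method, "'"))
  }

  structure(list(method = method, ctx = ctx,
                 exact_target = method %in% c("cpm", "da"),
                 has_mode = method %in% c("la", "cpm"),
                 log_marglik = log_marglik, refresh = refresh,
                 set_eta = set_eta, mode_eta = mode_eta,
                 draw_theta = draw_theta, set_g = set_g,
                 set_shape = set_shape,
                 log_marglik_at_shape = log_marglik_at_shape,
                 clear_cache = clear_cache),
            class = "marglik_engine")
}
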