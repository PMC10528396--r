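# Marginal-likelihood estimators p(y|gamma).
#
# Four routes are provided. The Laplace approximation (LA) integrates a
# second-order expansion at the posterior mode; the approximate Laplace
# approximation (ALA) expands at an arbitrary initial value and so avoids
# the Newton optimisation entirely; the adaptive ALA projects a running
# average of MAP linear predictors onto the model's column space and takes a
# single Newton step before applying ALA; and the correlated pseudo-marginal
# (CPM) estimator importance-samples the exact integral from the LA normal
# approximation, sharing its auxiliary normals across the two models of an
# MH ratio. Polya-gamma data augmentation (logistic only) lives in pg.R.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gradient / negated Hessian of the log posterior at theta (theta-space).
post_derivs <- function(theta, J, v, data, shape = NULL) {
  d <- ncol(J)
  eta <- if (d) drop(J %*% theta) else numeric(data$n)
  gr <- if (d) drop(crossprod(J, score_eta(eta, data, shape))) - theta / v
        else numeric(0)
  H <- if (d) xtwx(J, curvature_eta(eta, data, shape)) + diag(1 / v, d)
       else matrix(0, 0, 0)
  list(eta = eta, grad = gr, neg_hessian = H)
}

# Cholesky with a single jitter retry (1e-8 * mean diagonal); returns NULL
# if still indefinite so callers can treat the model as unreachable.
chol_jitter <- function(H) {
  if (!nrow(H)) return(H)
  out <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(out) && nrow(H)) {
    Hj <- H + diag(1e-8 * sum(diag(H)) / nrow(H), nrow(H))
    out <- tryCatch(chol(Hj), error = function(e) NULL)
  }
  out
}

#' Laplace approximation to the log marginal likelihood
#'
#' log p_LA(y|gamma) = log p(y|theta-hat) + log p(theta-hat|gamma)
#' + (d/2) log 2 pi - (1/2) log |H|, where theta-hat is the posterior mode
#' and H the negated Hessian of the log posterior at the mode.
#'
#' @inheritParams map_estimate
#' @param fit optional precomputed [map_estimate()] result.
#' @return list of class `"marglik_estimate"` with `log_value`, `estimator`,
#'   `mode`, the Cholesky factor of the negated Hessian, and `exact_target`
#'   (FALSE: the LA chain targets the LA posterior, not the exact one).
#' @export
log_marglik_la <- function(gamma, data, prior, shape = NULL, fit = NULL) {
  if (is.null(fit)) fit <- map_estimate(gamma, data, prior, shape = shape)
  d <- length(fit$theta)
  lv <- fit$value + 0.5 * d * log(2 * pi) - 0.5 * fit$logdet
  structure(list(log_value = lv, estimator = "LA", mode = fit$theta,
                 neg_hessian_chol = fit$R, fit = fit, exact_target = FALSE),
            class = "marglik_estimate")
}

#' Approximate Laplace approximation at a supplied initial value
#'
#' Expands the log posterior at `theta0` instead of the mode:
#' log p_ALA = log p(y|theta0) + log p(theta0|gamma) + (d/2) log 2 pi
#' - (1/2) log |H0| + (1/2) g0' H0^{-1} g0, with g0 and H0 the gradient and
#' Hessian of the negated log posterior at theta0. At theta0 = theta-hat the
#' gradient term vanishes and ALA coincides with LA.
#'
#' @inheritParams log_marglik_la
#' @param theta0 expansion point, length q + p_gamma (default: origin).
#' @export
log_marglik_ala <- function(gamma, data, prior, theta0 = NULL, shape = NULL) {
  idx <- gamma_index(gamma, data$p)
  J <- build_design(idx, data)
  d <- ncol(J)
  v <- prior_var_diag(prior, data$q, length(idx))
  if (is.null(theta0)) theta0 <- numeric(d)
  stopifnot(length(theta0) == d)
  f0 <- log_post_theta(theta0, J, v, data, shape)
  if (d == 0L)
    return(structure(list(log_value = f0, estimator = "ALA", mode = NULL,
                          exact_target = FALSE), class = "marglik_estimate"))
  pd <- post_derivs(theta0, J, v, data, shape)
  R <- chol_jitter(pd$neg_hessian)
  if (is.null(R))
    return(structure(list(log_value = -Inf, estimator = "ALA", mode = NULL,
                          exact_target = FALSE), class = "marglik_estimate"))
  # g0 (negated-posterior gradient) enters only through the quadratic form,
  # which is sign-invariant: g0' H^{-1} g0 with g0 = -grad.
  u <- backsolve(R, pd$grad, transpose = TRUE)
  lv <- f0 + 0.5 * d * log(2 * pi) - sum(log(diag(R))) + 0.5 * sum(u^2)
  structure(list(log_value = lv, estimator = "ALA", mode = NULL,
                 theta0 = theta0, exact_target = FALSE),
            class = "marglik_estimate")
}

# Least-squares projection of a linear predictor onto the model's column
# space, theta0 = (J'J)^{-1} J' eta, with a ridge fallback (lambda = 1e-8)
# for rank-deficient designs.
project_eta <- function(J, eta) {
  if (!ncol(J)) return(numeric(0))
  # normal equations with a Cholesky solve; QR then ridge as fallbacks for
  # (near-)rank-deficient designs
  A <- crossprod(J)
  b <- crossprod(J, eta)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R))
    return(drop(backsolve(R, backsolve(R, b, transpose = TRUE))))
  out <- tryCatch(qr.coef(qr(J), eta), error = function(e) NULL)
  if (is.null(out) || anyNA(out))
    out <- drop(solve(A + diag(1e-8, ncol(J)), b))
  as.numeric(out)
}

#' Adaptive ALA: project, one Newton step, then ALA
#'
#' Starting from a guess `eta_hat` of the optimal linear predictor (in the
#' sampler, the running average of MAP linear predictors of visited models),
#' computes theta0 by least squares, takes exactly one Newton step of the
#' log posterior, and evaluates the ALA at the updated point. When
#' `eta_hat` equals the model's own fitted MAP predictor the Newton step is
#' null and the estimate coincides with LA.
#'
#' @inheritParams log_marglik_la
#' @param eta_hat length-n initial guess of the linear predictor.
#' @export
log_marglik_adaptive_ala <- function(gamma, data, prior, eta_hat,
                                     shape = NULL) {
  idx <- gamma_index(gamma, data$p)
  J <- build_design(idx, data)
  d <- ncol(J)
  v <- prior_var_diag(prior, data$q, length(idx))
  fail <- structure(list(log_value = -Inf, estimator = "adaptiveALA",
                         exact_target = FALSE), class = "marglik_estimate")
  theta0 <- project_eta(J, eta_hat)
  if (d) {
    pd <- post_derivs(theta0, J, v, data, shape)
    R <- chol_jitter(pd$neg_hessian)
    if (is.null(R)) return(fail)
    # one Newton step: theta~ = theta0 - H^{-1} g0 = theta0 + H^{-1} grad
    theta0 <- theta0 + backsolve(R, backsolve(R, pd$grad, transpose = TRUE))
  }
  # ALA at the updated point, reusing the design built above
  f0 <- log_post_theta(theta0, J, v, data, shape)
  if (d == 0L)
    return(structure(list(log_value = f0, estimator = "adaptiveALA",
                          exact_target = FALSE), class = "marglik_estimate"))
  pd <- post_derivs(theta0, J, v, data, shape)
  R <- chol_jitter(pd$neg_hessian)
  if (is.null(R)) return(fail)
  uq <- backsolve(R, pd$grad, transpose = TRUE)
  lv <- f0 + 0.5 * d * log(2 * pi) - sum(log(diag(R))) + 0.5 * sum(uq^2)
  structure(list(log_value = lv, estimator = "adaptiveALA", theta0 = theta0,
                 exact_target = FALSE), class = "marglik_estimate")
}

#' Correlated pseudo-marginal estimate of the log marginal likelihood
#'
#' Unbiased importance-sampling estimate of p(y|gamma) with the LA normal
#' approximation as proposal: theta_i = theta-hat + R^{-1} u_i with
#' H = R'R, and p-hat = N^{-1} sum p(y|theta_i) p(theta_i|gamma) /
#' pi_LA(theta_i), assembled in log space. The auxiliary block `u` can be
#' supplied so that the two models of an MH ratio share the same normals;
#' inside the samplers `u` evolves by the autoregressive refresh
#' u' = rho u + sqrt(1 - rho^2) eps.
#'
#' @inheritParams log_marglik_la
#' @param u optional N x d_max matrix of standard normals (drawn if NULL).
#' @param N number of importance samples when `u` is NULL.
#' @export
log_marglik_cpm <- function(gamma, data, prior, u = NULL, N = 32L,
                            shape = NULL, fit = NULL) {
  idx <- gamma_index(gamma, data$p)
  if (is.null(fit)) fit <- map_estimate(idx, data, prior, shape = shape)
  d <- length(fit$theta)
  if (is.null(u)) u <- matrix(stats::rnorm(N * max(d, 1L)), nrow = N)
  stopifnot(N >= 1L, ncol(u) >= d)
  if (d == 0L) {
    lv <- fit$value
  } else {
    J <- build_design(idx, data)
    v <- prior_var_diag(prior, data$q, length(idx))
    U <- u[, seq_len(d), drop = FALSE]                  # N x d
    Theta <- fit$theta + backsolve(fit$R, t(U))         # d x N
    # log pi_LA(theta_i) simplifies because R (theta_i - theta-hat) = u_i
    log_q <- -0.5 * d * log(2 * pi) + 0.5 * fit$logdet -
      0.5 * rowSums(U^2)
    if (data$family == "cox") {
      lp <- vapply(seq_len(ncol(Theta)), function(i) {
        log_post_theta(Theta[, i], J, v, data, shape)
      }, numeric(1))
    } else {
      # diagonal families evaluate all importance samples in one GEMM
      Eta <- J %*% Theta                                # n x N
      ll <- if (data$family == "logistic") {
        colSums(data$y * Eta - softplus(Eta))
      } else {
        k <- if (is.null(shape)) data$shape else shape
        mlt <- pmin(k * (Eta + data$log_time), 690)
        colSums(data$event * (log(k) + k * Eta + (k - 1) * data$log_time) -
                  exp(mlt))
      }
      lp <- ll - 0.5 * colSums(Theta^2 / v) -
        0.5 * sum(log(2 * pi * v))
    }
    lv <- logsumexp(lp - log_q) - log(nrow(u))
  }
  structure(list(log_value = lv, estimator = "CPM", mode = fit$theta,
                 neg_hessian_chol = fit$R, fit = fit, exact_target = TRUE),
            class = "marglik_estimate")
}

#' @export
print.marglik_estimate <- function(x, ...) {
  cat(sprintf("log marginal likelihood (%s): %.6f\n", x$estimator,
              x$log_value))
  invisible(x)
}
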