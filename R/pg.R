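# Polya-gamma data augmentation for the logistic family.
#
# The augmentation identity (for psi real, a > 0, b > 0, omega ~ PG(b, 0)):
#   exp(psi)^a / (1 + exp(psi))^b = 2^{-b} exp(kappa psi) E[exp(-omega psi^2/2)]
# with kappa = a - b/2 turns each Bernoulli likelihood factor into a Gaussian
# kernel in the linear predictor, so conditional on omega the coefficient
# posterior is exactly normal and the conditional marginal likelihood has a
# closed form. The chain alternates gamma | omega moves (with the
# conditional marginal likelihood as target) and omega | gamma refreshes
# omega_i ~ PG(1, eta_i); it targets the exact posterior.

#' Draw Polya-gamma PG(1, z) variates
#'
#' Exact Devroye-type alternating-series sampler (no truncation error).
#'
#' @param z numeric vector of tilts; one draw per element.
#' @return numeric vector of positive draws, same length as `z`.
#' @export
rpg1 <- function(z) .rpg1(as.numeric(z))

#' Monte-Carlo check of the Polya-gamma identity
#'
#' Estimates 2^{-b} exp(kappa psi) E[exp(-omega psi^2 / 2)] with
#' omega ~ PG(b, 0) and kappa = a - b/2, which equals
#' exp(psi)^a / (1 + exp(psi))^b. `b` must be a positive integer (PG(b, 0)
#' is drawn as a sum of b PG(1, 0) variates).
#'
#' @param psi real scalar.
#' @param a,b identity parameters, b a positive integer.
#' @param n_mc number of Monte-Carlo draws.
#' @return list with the MC `estimate`, its standard error `se`, and the
#'   closed-form left-hand side `exact`.
#' @export
pg_identity_rhs <- function(psi, a, b, n_mc = 1e5) {
  stopifnot(b > 0, b == round(b))
  omega <- rowSums(matrix(rpg1(rep(0, n_mc * b)), ncol = b))
  kappa <- a - b / 2
  vals <- 2^(-b) * exp(kappa * psi) * exp(-omega * psi^2 / 2)
  list(estimate = mean(vals), se = stats::sd(vals) / sqrt(n_mc),
       exact = exp(a * psi - b * softplus(psi)))
}

#' Refresh the Polya-gamma latent variables
#'
#' omega_i ~ PG(1, eta_i) with eta the linear predictor of the current model
#' and coefficients.
#'
#' @param gamma model indicator.
#' @param theta coefficient vector for `gamma`.
#' @param data a [bvs_data()] object with `family = "logistic"`.
#' @return positive vector omega of length n.
#' @export
pg_update_omega <- function(gamma, theta, data) {
  stopifnot(data$family == "logistic")
  J <- build_design(gamma, data)
  eta <- if (ncol(J)) drop(J %*% theta) else numeric(data$n)
  rpg1(eta)
}

# Internal: Cholesky pieces of the conditional Gaussian given omega.
pg_gaussian_parts <- function(idx, omega, data, prior) {
  J <- build_design(idx, data)
  v <- prior_var_diag(prior, data$q, length(idx))
  kappa <- data$y - 0.5
  Lambda <- xtwx(J, omega) + diag(1 / v, ncol(J))
  xi <- drop(crossprod(J, kappa))
  R <- if (ncol(J)) chol(Lambda) else matrix(0, 0, 0)
  list(R = R, xi = xi, v = v, d = ncol(J))
}

#' Conditional log marginal likelihood given Polya-gamma variables
#'
#' log p(y|gamma, omega) = -n log 2 - (1/2) log|V| - (1/2) log|Lambda|
#' + (1/2) xi' Lambda^{-1} xi, with xi = J' kappa, kappa_i = y_i - 1/2 and
#' Lambda = J' diag(omega) J + V^{-1}. The additive constant (-n log 2) is
#' the exact Gaussian-integral constant, fixed across gamma for fixed omega,
#' so the same value serves MH ratios and diagnostics.
#'
#' @param gamma model indicator.
#' @param omega positive vector of Polya-gamma draws, length n.
#' @param data logistic [bvs_data()] object.
#' @param prior a [bvs_prior()] object.
#' @return scalar log conditional marginal likelihood.
#' @export
pg_conditional_marglik <- function(gamma, omega, data, prior) {
  stopifnot(data$family == "logistic")
  idx <- gamma_index(gamma, data$p)
  gp <- pg_gaussian_parts(idx, omega, data, prior)
  u <- if (gp$d) backsolve(gp$R, gp$xi, transpose = TRUE) else numeric(0)
  -data$n * log(2) - 0.5 * sum(log(gp$v)) - sum(log(diag(gp$R))) +
    0.5 * sum(u^2)
}

#' Exact draw of the coefficients given Polya-gamma variables
#'
#' theta | gamma, omega, y ~ N(Lambda^{-1} xi, Lambda^{-1}), drawn by
#' triangular solves.
#'
#' @inheritParams pg_conditional_marglik
#' @return coefficient vector of length q + p_gamma.
#' @export
pg_draw_theta <- function(gamma, omega, data, prior) {
  stopifnot(data$family == "logistic")
  idx <- gamma_index(gamma, data$p)
  gp <- pg_gaussian_parts(idx, omega, data, prior)
  if (gp$d == 0L) return(numeric(0))
  m <- backsolve(gp$R, backsolve(gp$R, gp$xi, transpose = TRUE))
  m + backsolve(gp$R, stats::rnorm(gp$d))
}
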