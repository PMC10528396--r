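#' Prior specification for spike-and-slab variable selection
#'
#' The slab is independent Gaussian: alpha ~ N(0, sigma_alpha2 I_q) on the
#' fixed covariates and beta_gamma | gamma ~ N(0, g I_{p_gamma}) on the
#' selected ones. The model prior is either the independent-Bernoulli form
#' h^{p_gamma} (1-h)^{p - p_gamma} with fixed inclusion probability `h`, or
#' the Beta-binomial form B(a + p_gamma, b + p - p_gamma) / B(a, b) obtained
#' by integrating a Beta(a, b) hyper-prior on h. For the Weibull family a
#' N(0, sigma_k2) prior sits on log k.
#'
#' @param g positive slab variance, or the string `"half_cauchy"` to flag
#'   that g is a sampled hyper-parameter (an initial numeric value is then
#'   taken from `g_init`).
#' @param sigma_alpha2 prior variance of the fixed-covariate coefficients.
#' @param h fixed prior inclusion probability in (0,1); supply either `h` or
#'   `(a, b)`.
#' @param a,b Beta-binomial hyper-parameters (both > 0).
#' @param sigma_k2 prior variance of log k (Weibull only).
#' @param g_init initial g when `g = "half_cauchy"`.
#' @return object of class `"bvs_prior"`.
#' @export
bvs_prior <- function(g = 1, sigma_alpha2 = 100, h = NULL, a = NULL, b = NULL,
                      sigma_k2 = 100, g_init = 1) {
  learn_g <- identical(g, "half_cauchy")
  if (learn_g) g <- g_init
  stopifnot(is.numeric(g), g > 0, sigma_alpha2 > 0, sigma_k2 > 0)
  if (is.null(h) && is.null(a)) h <- 0.5
  if (!is.null(h)) {
    stopifnot(h > 0, h < 1, is.null(a), is.null(b))
    model_prior <- "fixed"
  } else {
    stopifnot(a > 0, b > 0)
    model_prior <- "betabinomial"
  }
  structure(list(g = g, learn_g = learn_g, sigma_alpha2 = sigma_alpha2,
                 h = h, a = a, b = b, sigma_k2 = sigma_k2,
                 model_prior = model_prior),
            class = "bvs_prior")
}

# Diagonal of the prior covariance V_gamma = blockdiag(sigma_alpha2 I_q, g I).
prior_var_diag <- function(prior, q, p_gamma) {
  c(rep(prior$sigma_alpha2, q), rep(prior$g, p_gamma))
}

#' Log-density of the coefficient prior
#'
#' Independent zero-mean Gaussians: N(0, sigma_alpha2) on each of the q fixed
#' coefficients, N(0, g) on each selected coefficient and, when `log_k` is
#' supplied, N(0, sigma_k2) on the Weibull log-shape.
#'
#' @param theta coefficient vector (alpha first, then beta_gamma).
#' @param gamma model indicator.
#' @param prior a [bvs_prior()] object.
#' @param q number of fixed covariates.
#' @param log_k optional log-shape value (Weibull).
#' @return scalar log prior density.
#' @export
log_coef_prior <- function(theta, gamma = NULL, prior, q = 0L, log_k = NULL) {
  p_gamma <- length(theta) - q
  stopifnot(p_gamma >= 0)
  v <- prior_var_diag(prior, q, p_gamma)
  out <- if (length(v)) sum(stats::dnorm(theta, 0, sqrt(v), log = TRUE)) else 0
  if (!is.null(log_k))
    out <- out + stats::dnorm(log_k, 0, sqrt(prior$sigma_k2), log = TRUE)
  out
}

#' Log model prior p(gamma)
#'
#' @param gamma model indicator (indices or 0/1 vector).
#' @param prior a [bvs_prior()] object.
#' @param p total number of selectable covariates.
#' @return scalar log prior mass.
#' @export
log_model_prior <- function(gamma, prior, p) {
  pg <- length(gamma_index(gamma, p))
  log_model_prior_size(pg, prior, p)
}

# Same, from the model size only (the priors depend on gamma through p_gamma).
log_model_prior_size <- function(pg, prior, p) {
  if (prior$model_prior == "fixed") {
    pg * log(prior$h) + (p - pg) * log1p(-prior$h)
  } else {
    lbeta(prior$a + pg, prior$b + p - pg) - lbeta(prior$a, prior$b)
  }
}

# Log prior ratio p(gamma with j added) / p(gamma without j), given the size
# of the smaller model.
log_prior_inclusion_ratio <- function(pg_without, prior, p) {
  log_model_prior_size(pg_without + 1L, prior, p) -
    log_model_prior_size(pg_without, prior, p)
}
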