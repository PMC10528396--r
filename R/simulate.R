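# Synthetic data with the structure of a high-dimensional variable-selection
# study: correlated Gaussian designs, a sparse true support, and binary or
# right-censored responses. Defaults echo a 500 x 500 simulation with ten
# true effects of alternating sign on an AR(1) design and 30% censoring for
# the survival families; everything is configurable.

ar1_design <- function(n, p, rho) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho != 0 && p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + s * X[, j]
  }
  X
}

block_design <- function(n, p, size, rho) {
  X <- matrix(0, n, p)
  for (start in seq(1, p, by = size)) {
    cols <- start:min(start + size - 1, p)
    Z0 <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * length(cols)), n)
    X[, cols] <- sqrt(rho) * Z0 + sqrt(1 - rho) * E
  }
  X
}

standardise_cols <- function(X) {
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

# Calibrate an exponential censoring rate by bisection so that the expected
# censoring fraction matches the target.
calibrate_censoring <- function(T_lat, target, tol = 1e-4) {
  if (target <= 0) return(0)
  # P(C < T | T = t) = 1 - exp(-r t) for C ~ Exp(r); solve
  # mean(1 - exp(-r T)) = target in r by bisection on log r.
  f <- function(lr) mean(1 - exp(-exp(lr) * T_lat)) - target
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    warning("censoring target ", target, " not achievable; using boundary")
    return(exp(if (f(lo) > 0) lo else hi))
  }
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  exp((lo + hi) / 2)
}

#' Simulate a variable-selection data set
#'
#' Rows of X are iid Gaussian with the chosen correlation structure and
#' columns are standardised to mean 0, sd 1. The linear predictor is
#' eta = Z alpha + X_S beta_S over the true support S. Logistic responses
#' are Bernoulli(logit^-1(eta)); survival times follow a Weibull with
#' hazard scale lambda_i = exp(eta_i) and shape `weibull_k` (the Cox family
#' uses the same generator and simply ignores the baseline when analysed),
#' censored by an exponential time whose rate is calibrated by bisection to
#' the target censoring fraction.
#'
#' @param n,p observations and selectable covariates.
#' @param family `"logistic"`, `"cox"` or `"weibull"`.
#' @param true_support indices of the active covariates (default: 10 evenly
#'   spaced positions).
#' @param effect_sizes coefficients on the support (default: alternating
#'   +/- 1).
#' @param correlation `"independent"`, `"ar1"` or `"block"`.
#' @param rho correlation parameter (AR(1) neighbour correlation or within-
#'   block correlation).
#' @param block_size block width for `correlation = "block"`.
#' @param q_extra standard-normal fixed covariates beyond the intercept.
#' @param intercept include an intercept column in Z (dropped for Cox,
#'   whose partial likelihood is location-free).
#' @param censoring_rate target censoring fraction (survival families).
#' @param weibull_k true shape parameter of the survival-time generator.
#' @return list with the [bvs_data()] object `data` and a `truth` record
#'   (support, beta, alpha, k, achieved censoring).
#' @export
simulate_bvs <- function(n = 500, p = 500,
                         family = c("logistic", "cox", "weibull"),
                         true_support = NULL, effect_sizes = NULL,
                         correlation = c("ar1", "independent", "block"),
                         rho = 0.6, block_size = 10, q_extra = 0,
                         intercept = NULL, censoring_rate = 0.3,
                         weibull_k = 1.5) {
  family <- match.arg(family)
  correlation <- match.arg(correlation)
  if (is.null(true_support))
    true_support <- unique(round(seq(1, p, length.out = min(10, p))))
  if (is.null(effect_sizes))
    effect_sizes <- rep_len(c(1, -1), length(true_support))
  stopifnot(length(true_support) == length(effect_sizes),
            all(true_support >= 1), all(true_support <= p))
  if (is.null(intercept)) intercept <- family != "cox"
  X <- switch(correlation,
              independent = matrix(stats::rnorm(n * p), n, p),
              ar1 = ar1_design(n, p, rho),
              block = block_design(n, p, block_size, rho))
  X <- standardise_cols(X)
  Z <- NULL
  alpha <- numeric(0)
  if (intercept) { Z <- cbind(Z, rep(1, n)); alpha <- c(alpha, 0) }
  if (q_extra > 0) {
    Z <- cbind(Z, matrix(stats::rnorm(n * q_extra), n))
    alpha <- c(alpha, numeric(q_extra))
  }
  eta <- drop(X[, true_support, drop = FALSE] %*% effect_sizes)
  if (!is.null(Z)) eta <- eta + drop(Z %*% alpha)

  if (family == "logistic") {
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    data <- bvs_data(X, y = y, z = Z, family = "logistic")
    truth <- list(support = true_support, beta = effect_sizes,
                  alpha = alpha)
  } else {
    lambda <- exp(eta)
    T_lat <- (-log(stats::runif(n)))^(1 / weibull_k) / lambda
    rate <- calibrate_censoring(T_lat, censoring_rate)
    C_lat <- if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
    t_obs <- pmin(T_lat, C_lat)
    d_obs <- as.numeric(T_lat <= C_lat)
    data <- bvs_data(X, time = t_obs, event = d_obs, z = Z, family = family,
                     shape = 1)
    truth <- list(support = true_support, beta = effect_sizes,
                  alpha = alpha, k = weibull_k,
                  censoring = mean(d_obs == 0))
    if (censoring_rate > 0 &&
        abs(truth$censoring - censoring_rate) > 0.1)
      warning(sprintf("achieved censoring %.2f differs from target %.2f",
                      truth$censoring, censoring_rate))
  }
  list(data = data, truth = truth)
}

#' Small enumerable fixture for sampler validation
#'
#' A seed-deterministic data set small enough that all 2^p models can be
#' enumerated with any engine in seconds, with strong well-separated
#' effects so the posterior concentrates on the truth.
#'
#' @param family model family.
#' @param seed RNG seed (set internally; the fixture is reproducible).
#' @param n,p dimensions (n in 40..200 and p in 4..10 keep enumeration
#'   cheap).
#' @return list with `data` and `truth`, as [simulate_bvs()].
#' @export
make_enumerable_fixture <- function(family = "logistic", seed = 1,
                                    n = 200, p = 8) {
  stopifnot(n >= 40, n <= 200, p >= 4, p <= 10)
  set.seed(seed)
  support <- seq(1, p, by = 3)
  simulate_bvs(n = n, p = p, family = family, true_support = support,
               effect_sizes = rep_len(c(1.5, -1.5), length(support)),
               correlation = "independent", censoring_rate = 0.2,
               weibull_k = 1.5)
}
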