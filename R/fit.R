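#' Bayesian variable selection by adaptive model-space MCMC
#'
#' Fits a spike-and-slab variable-selection model by sampling model
#' indicators directly from their marginal posterior. The default sampler
#' is the point-wise adaptive random neighbourhood informed (PARNI)
#' proposal, with an adaptive approximate-Laplace informed proposal and a
#' correlated pseudo-marginal acceptance step; `sampler = "ads"` gives the
#' add-delete-swap baseline. For the logistic family the Polya-gamma
#' data-augmentation engine (`"da"`) targets the exact posterior in both
#' roles.
#'
#' @param x numeric matrix of candidate covariates (n x p).
#' @param y response: a 0/1 vector (logistic) or a [survival::Surv] object /
#'   two-column matrix of (time, event) for the survival families.
#' @param z optional matrix of covariates forced into every model.
#' @param family `"logistic"`, `"cox"` or `"weibull"`. Defaults to
#'   `"logistic"` for a binary `y` and `"cox"` for a `Surv` response.
#' @param sampler `"parni"` or `"ads"`.
#' @param proposal_engine marginal-likelihood engine used inside the
#'   informed proposal (PARNI only): `"adaptive_ala"`, `"la"`, `"ala"`,
#'   `"cpm"` or `"da"`.
#' @param acceptance_engine engine used in the MH acceptance probability:
#'   `"cpm"`, `"la"` or `"da"`.
#' @param n_iter,burnin total iterations and burn-in length.
#' @param prior a [bvs_prior()]; by default g = 1/4, sigma_alpha2 = 1 and a
#'   Beta-binomial(1, max(1, (p-5)/5)) model prior.
#' @param intercept prepend an intercept column to `z` (ignored for Cox,
#'   whose partial likelihood is location-invariant).
#' @param epsilon adaptation clip parameter in (0, 1/2).
#' @param zeta initial non-informative jumping probability.
#' @param adapt_zeta adapt zeta by Robbins-Monro toward `alpha_target`?
#' @param alpha_target target acceptance rate for the zeta adaptation.
#' @param learn_k sample the Weibull shape k by adaptive random walk?
#' @param gamma0 initial model (integer indices; default empty).
#' @param shape initial/fixed Weibull shape.
#' @param cpm_N,cpm_rho correlated pseudo-marginal settings.
#' @param seed optional integer passed to [set.seed()] before sampling.
#' @param store_models keep the full sampled model sequence?
#'
#' @return An object of class `"parni"` with posterior inclusion
#'   probabilities (`pip`, post-burn-in), the log-posterior trace, per-
#'   iteration acceptance flags and neighbourhood sizes, adapted tuning
#'   parameters, and (if requested) the sampled models.
#' @examples
#' sim <- make_enumerable_fixture("logistic", seed = 42, n = 150, p = 6)
#' fit <- parni(sim$data$x, sim$data$y, z = sim$data$z,
#'              proposal_engine = "la", acceptance_engine = "la",
#'              n_iter = 500, burnin = 100, intercept = FALSE, seed = 1)
#' round(fit$pip, 2)
#' @export
parni <- function(x, y, z = NULL, family = NULL,
                  sampler = c("parni", "ads"),
                  proposal_engine = c("adaptive_ala", "la", "ala", "cpm",
                                      "da"),
                  acceptance_engine = c("cpm", "la", "da"),
                  n_iter = 10000L, burnin = 2000L, prior = NULL,
                  intercept = TRUE, epsilon = 0.001, zeta = 0.5,
                  adapt_zeta = TRUE, alpha_target = 0.234,
                  learn_k = FALSE, gamma0 = integer(0), shape = 1,
                  cpm_N = 32L, cpm_rho = 0.99, seed = NULL,
                  store_models = FALSE) {
  sampler <- match.arg(sampler)
  proposal_engine <- match.arg(proposal_engine)
  acceptance_engine <- match.arg(acceptance_engine)
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)

  is_surv <- survival::is.Surv(y) || (is.matrix(y) && ncol(y) == 2)
  if (is.null(family)) family <- if (is_surv) "cox" else "logistic"
  family <- match.arg(family, c("logistic", "cox", "weibull"))
  if (family == "cox") intercept <- FALSE
  if (intercept) z <- cbind(`(Intercept)` = rep(1, nrow(as.matrix(x))), z)
  if (family == "logistic") {
    data <- bvs_data(x, y = y, z = z, family = "logistic")
  } else {
    ym <- as.matrix(y)
    data <- bvs_data(x, time = ym[, 1], event = ym[, 2], z = z,
                     family = family, shape = shape)
  }
  if (is.null(prior))
    prior <- bvs_prior(g = 0.25, sigma_alpha2 = 1, a = 1,
                       b = max(1, (data$p - 5) / 5))
  stopifnot(burnin < n_iter)
  if (acceptance_engine == "da" && data$family != "logistic")
    stop("the data-augmentation engine requires the logistic family")

  acc <- marglik_engine(acceptance_engine, data, prior, N = cpm_N,
                        rho = cpm_rho)
  if (sampler == "parni") {
    prop <- if (proposal_engine == acceptance_engine) acc
            else marglik_engine(proposal_engine, data, prior, N = cpm_N,
                                rho = cpm_rho)
    res <- run_parni_chain(data, prior, prop, acc, n_iter = n_iter,
                           burnin = burnin, epsilon = epsilon, zeta = zeta,
                           adapt_zeta = adapt_zeta,
                           alpha_target = alpha_target, gamma0 = gamma0,
                           learn_g = prior$learn_g, learn_k = learn_k,
                           store_models = store_models)
  } else {
    res <- run_ads_chain(data, prior, acc, n_iter = n_iter, burnin = burnin,
                         gamma0 = gamma0, learn_g = prior$learn_g,
                         learn_k = learn_k, store_models = store_models)
  }
  res$call <- cl
  res$data <- data
  res$prior <- prior
  res$sampler <- sampler
  res$family <- data$family
  res$engines <- c(proposal = if (sampler == "parni") proposal_engine
                              else NA_character_,
                   acceptance = acceptance_engine)
  res$acceptance_engine <- acc
  res$varnames <- colnames(data$x)
  if (is.null(res$varnames)) res$varnames <- paste0("x", seq_len(data$p))
  class(res) <- "parni"
  res
}
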