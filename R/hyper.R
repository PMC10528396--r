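# Hyper-parameter moves used inside the samplers.

#' Gibbs update of the slab variance g under a half-Cauchy hyper-prior
#'
#' The half-Cauchy scale prior sqrt(g) ~ C+(0, 1) is represented as an
#' inverse-gamma mixture: g | a_aux ~ IG(1/2, 1/a_aux) with
#' a_aux ~ IG(1/2, 1). Conditional on a coefficient draw beta_gamma the
#' update is two exact inverse-gamma draws:
#' g | beta, a_aux ~ IG((p_gamma + 1)/2, beta'beta/2 + 1/a_aux) and
#' a_aux | g ~ IG(1, 1 + 1/g). With p_gamma = 0 the composed kernel
#' leaves the prior invariant.
#'
#' @param hyper list with current `g` and auxiliary `aux`.
#' @param beta current draw of the selected coefficients (may be empty).
#' @return the updated hyper list.
#' @export
update_g <- function(hyper, beta = numeric(0)) {
  pg <- length(beta)
  hyper$aux <- 1 / stats::rgamma(1, shape = 1, rate = 1 + 1 / hyper$g)
  hyper$g <- 1 / stats::rgamma(1, shape = (pg + 1) / 2,
                               rate = sum(beta^2) / 2 + 1 / hyper$aux)
  hyper
}

#' Adaptive random-walk update of the Weibull shape
#'
#' MH step log k' = log k + s * eps with eps ~ N(0,1), accepted against the
#' acceptance-side marginal-likelihood estimate at k' versus k times the
#' N(0, sigma_k2) prior ratio on log k (the proposal is symmetric and
#' cancels). The step size s adapts by Robbins-Monro toward acceptance rate
#' 0.44 with diminishing step l^{-0.7}.
#'
#' @param hyper list with `log_k` and `rw_scale`.
#' @param idx current model (integer indices).
#' @param engine acceptance-side [marglik_engine()].
#' @param prior a [bvs_prior()] object.
#' @param iter current iteration number (drives the adaptation step size).
#' @return the updated hyper list; `k_accepted` flags whether k moved.
#' @export
update_log_k <- function(hyper, idx, engine, prior, iter) {
  lk_new <- hyper$log_k + hyper$rw_scale * stats::rnorm(1)
  cur <- engine$log_marglik(idx) +
    stats::dnorm(hyper$log_k, 0, sqrt(prior$sigma_k2), log = TRUE)
  prop <- engine$log_marglik_at_shape(idx, exp(lk_new)) +
    stats::dnorm(lk_new, 0, sqrt(prior$sigma_k2), log = TRUE)
  accepted <- log(stats::runif(1)) < prop - cur
  if (accepted) hyper$log_k <- lk_new
  hyper$rw_scale <- exp(log(hyper$rw_scale) +
                          iter^(-0.7) * (as.numeric(accepted) - 0.44))
  hyper$k_accepted <- accepted
  hyper
}
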