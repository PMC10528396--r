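# Likelihood families in linear-predictor space.
#
# Every marginal-likelihood engine works through three primitives evaluated
# at an arbitrary eta = J_gamma theta: the log-likelihood, its score
# dl/deta_i, and the negated second derivative ("curvature") W. For the
# logistic and Weibull families W is diagonal and returned as a length-n
# vector; the Cox partial likelihood couples subjects through shared risk
# sets and returns a dense n x n matrix (O(n^2) storage and work).

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Cox bookkeeping in ascending time order: risk-set sums and the cumulative
# event weights 1/S_j and 1/S_j^2 needed by score and curvature. Breslow
# convention for ties: every event keeps its own term, the risk set is
# {i : t_i >= t_j}, so tied subjects appear in each other's risk sets.
cox_parts <- function(eta, data) {
  ord <- data$cox_ord
  to <- data$time[ord]
  do <- data$event[ord]
  m <- max(eta)
  eo <- exp(eta[ord] - m)                       # shifted exponentials
  rcs <- rev(cumsum(rev(eo)))
  fp <- which(!duplicated(to))                  # first position of tied block
  fpos <- rep(fp, diff(c(fp, length(to) + 1L))) # block start for each subject
  lp <- c(fp[-1L] - 1L, length(to))
  lpos <- rep(lp, diff(c(fp, length(to) + 1L))) # block end for each subject
  S <- rcs[fpos]                                # risk sum at each subject's time
  c1 <- ifelse(do == 1, 1 / S, 0)
  c2 <- ifelse(do == 1, 1 / S^2, 0)
  G1 <- cumsum(c1)[lpos]                        # sum over events with t_j <= t_i
  G2 <- cumsum(c2)[lpos]
  list(ord = ord, m = m, eo = eo, do = do, S = S, G1 = G1, G2 = G2)
}

#' Log-likelihood of a coefficient vector under a model
#'
#' Evaluates the family log-likelihood at `theta` for the design
#' `J_gamma = (Z, X_gamma)`. For the Cox family this is the Breslow log
#' partial likelihood; for the Weibull family the shape k enters through
#' `shape` (or the value stored in `data`).
#'
#' @param theta numeric vector of length q + p_gamma.
#' @param gamma model indicator (indices or 0/1 vector).
#' @param data a [bvs_data()] object.
#' @param shape Weibull shape parameter; defaults to `data$shape`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, gamma, data, shape = NULL) {
  J <- build_design(gamma, data)
  eta <- if (ncol(J)) drop(J %*% theta) else numeric(data$n)
  loglik_eta(eta, data, shape)
}

# Log-likelihood as a function of the linear predictor.
loglik_eta <- function(eta, data, shape = NULL) {
  switch(data$family,
    logistic = sum(data$y * eta - softplus(eta)),
    cox = {
      cp <- cox_parts(eta, data)
      ev <- cp$do == 1
      sum((log(cp$eo[ev]) + cp$m) - (log(cp$S[ev]) + cp$m))
    },
    weibull = {
      k <- if (is.null(shape)) data$shape else shape
      mlt <- pmin(k * (eta + data$log_time), 690)
      sum(data$event * (log(k) + k * eta + (k - 1) * data$log_time) -
            exp(mlt))
    })
}

# Score dl/deta (length n) at eta.
score_eta <- function(eta, data, shape = NULL) {
  switch(data$family,
    logistic = data$y - stats::plogis(eta),
    cox = {
      cp <- cox_parts(eta, data)
      u <- cp$do - cp$eo * cp$G1
      out <- numeric(data$n)
      out[cp$ord] <- u
      out
    },
    weibull = {
      k <- if (is.null(shape)) data$shape else shape
      mlt <- pmin(k * (eta + data$log_time), 690)
      k * (data$event - exp(mlt))
    })
}

# Curvature W = -d^2 l/deta^2: length-n vector (diagonal) for logistic and
# Weibull, dense n x n matrix for Cox.
curvature_eta <- function(eta, data, shape = NULL) {
  switch(data$family,
    logistic = {
      mu <- stats::plogis(eta)
      mu * (1 - mu)
    },
    cox = {
      cp <- cox_parts(eta, data)
      n <- data$n
      idx <- seq_len(n)
      Wo <- -outer(cp$eo, cp$eo) * cp$G2[outer(idx, idx, pmin)]
      diag(Wo) <- diag(Wo) + cp$eo * cp$G1
      W <- matrix(0, n, n)
      W[cp$ord, cp$ord] <- Wo
      W
    },
    weibull = {
      k <- if (is.null(shape)) data$shape else shape
      mlt <- pmin(k * (eta + data$log_time), 690)
      k^2 * exp(mlt)
    })
}

#' Score and curvature of the log-likelihood in linear-predictor space
#'
#' Returns the first derivative vector y-tilde (component i equal to
#' dl/deta_i) and the negated second-derivative operator W evaluated at a
#' reference linear predictor. At eta = 0 these drive both the
#' approximate-Laplace estimate at the origin and the Schur-complement
#' warm-start Bayes factors.
#'
#' @inheritParams log_likelihood
#' @param eta reference linear predictor, length n.
#' @return list with `y_tilde` (length n), `W` (length-n vector for diagonal
#'   families, dense matrix for Cox) and `reference_eta`.
#' @export
eta_score_curvature <- function(eta, gamma = NULL, data, shape = NULL) {
  list(y_tilde = score_eta(eta, data, shape),
       W = curvature_eta(eta, data, shape),
       reference_eta = eta)
}

# J^T W J and J^T W x products without assuming W diagonal.
xtwx <- function(J, W) {
  if (is.matrix(W)) crossprod(J, W %*% J) else crossprod(J * sqrt(W))
}
xtwv <- function(J, W, v) {
  if (is.matrix(W)) crossprod(J, W %*% v) else crossprod(J, W * v)
}
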