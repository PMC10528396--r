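# S3 methods for fitted "parni" objects.

#' @export
print.parni <- function(x, ...) {
  cat("Bayesian variable selection (", x$sampler, " sampler, ", x$family,
      " family)\n", sep = "")
  cat(sprintf("  %d iterations (%d burn-in), acceptance rate %.3f\n",
              x$n_iter, x$burnin, x$acceptance_rate))
  top <- order(x$pip, decreasing = TRUE)[seq_len(min(5, length(x$pip)))]
  cat("  top posterior inclusion probabilities:\n")
  for (j in top)
    cat(sprintf("    %-12s %.3f\n", x$varnames[j], x$pip[j]))
  invisible(x)
}

#' Summarise a fitted variable-selection run
#'
#' @param object a fitted [parni()] object.
#' @param pip_threshold inclusion cut-off defining the reported
#'   median-probability model.
#' @param ... unused.
#' @export
summary.parni <- function(object, pip_threshold = 0.5, ...) {
  sel <- which(object$pip > pip_threshold)
  out <- list(
    sampler = object$sampler, family = object$family,
    engines = object$engines,
    n_iter = object$n_iter, burnin = object$burnin,
    acceptance_rate = object$acceptance_rate,
    mean_model_size = mean(object$p_gamma[-seq_len(object$burnin)]),
    pip = stats::setNames(object$pip, object$varnames),
    selected = stats::setNames(sel, object$varnames[sel]),
    pip_threshold = pip_threshold)
  class(out) <- "summary.parni"
  out
}

#' @export
print.summary.parni <- function(x, ...) {
  cat("Model-space MCMC summary\n")
  cat(sprintf("  sampler: %s  family: %s\n", x$sampler, x$family))
  cat(sprintf("  iterations: %d (burn-in %d), acceptance rate %.3f\n",
              x$n_iter, x$burnin, x$acceptance_rate))
  cat(sprintf("  mean post-burn-in model size: %.2f\n", x$mean_model_size))
  cat(sprintf("  covariates with PIP > %.2f: %d\n", x$pip_threshold,
              length(x$selected)))
  if (length(x$selected)) {
    for (nm in names(x$selected))
      cat(sprintf("    %-12s %.3f\n", nm, x$pip[[x$selected[[nm]]]]))
  }
  invisible(x)
}

#' Coefficients of the median-probability model
#'
#' Returns the posterior-mode (MAP) coefficients of the model containing
#' every covariate with PIP above the threshold, conditional on that model.
#'
#' @param object a fitted [parni()] object.
#' @param pip_threshold inclusion cut-off (0.5 gives the median-probability
#'   model).
#' @param ... unused.
#' @export
coef.parni <- function(object, pip_threshold = 0.5, ...) {
  sel <- which(object$pip > pip_threshold)
  fit <- map_estimate(sel, object$data, final_prior(object),
                      shape = final_shape(object))
  q <- object$data$q
  nm <- c(colnames(object$data$z), object$varnames[sel])
  if (is.null(colnames(object$data$z)) && q > 0)
    nm <- c(paste0("z", seq_len(q)), object$varnames[sel])
  stats::setNames(fit$theta, nm)
}

final_shape <- function(object) {
  if (object$family != "weibull") return(NULL)
  if (!is.null(object$k_trace)) utils::tail(object$k_trace, 1)
  else object$data$shape
}

# Prior with the last sampled slab variance when g was learned.
final_prior <- function(object) {
  prior <- object$prior
  if (!is.null(object$g_trace)) prior$g <- utils::tail(object$g_trace, 1)
  prior
}

#' Linear predictor / fitted response for new data
#'
#' Uses the conditional MAP coefficients of the median-probability model.
#'
#' @param object a fitted [parni()] object.
#' @param newdata matrix of candidate covariates (and `newz` for the fixed
#'   ones); defaults to the training data.
#' @param newz matrix of fixed covariates matching `newdata`.
#' @param type `"link"` for the linear predictor or `"response"` for the
#'   event probability (logistic) / hazard scale exp(eta) (survival).
#' @param pip_threshold inclusion cut-off for the reported model.
#' @param ... unused.
#' @export
predict.parni <- function(object, newdata = NULL, newz = NULL,
                          type = c("link", "response"),
                          pip_threshold = 0.5, ...) {
  type <- match.arg(type)
  sel <- which(object$pip > pip_threshold)
  fit <- map_estimate(sel, object$data, final_prior(object),
                      shape = final_shape(object))
  if (is.null(newdata)) {
    X <- object$data$x
    Z <- object$data$z
  } else {
    X <- as.matrix(newdata)
    Z <- if (object$data$q) {
      if (is.null(newz)) stop("newz required: the model has fixed covariates")
      as.matrix(newz)
    } else matrix(numeric(0), nrow(X), 0)
  }
  J <- cbind(Z, X[, sel, drop = FALSE])
  eta <- if (ncol(J)) drop(J %*% fit$theta) else numeric(nrow(X))
  if (type == "link") eta
  else if (object$family == "logistic") stats::plogis(eta)
  else exp(eta)
}

#' Trace and inclusion-probability plot
#'
#' Left panel: log-posterior trace of the sampled models. Right panel:
#' posterior inclusion probabilities.
#'
#' @param x a fitted [parni()] object.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.parni <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log_post, type = "l", xlab = "iteration",
                 ylab = "log posterior (model)", main = "trace", ...)
  graphics::abline(v = x$burnin, lty = 2)
  graphics::plot(x$pip, type = "h", ylim = c(0, 1), xlab = "covariate",
                 ylab = "PIP", main = "inclusion probabilities")
  invisible(x)
}
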