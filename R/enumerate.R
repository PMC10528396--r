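#' Exact posterior over the model lattice by full enumeration
#'
#' Evaluates the chosen engine's log p(y|gamma) + log p(gamma) for all 2^p
#' models, normalises to posterior model probabilities (PMPs) and
#' marginalises to posterior inclusion probabilities (PIPs). This is the
#' gold-standard oracle against which the samplers are validated on small
#' problems.
#'
#' @param data a [bvs_data()] object with `p <= p_max`.
#' @param prior a [bvs_prior()] object.
#' @param engine a [marglik_engine()] object, an engine name (`"la"`,
#'   `"ala"`, ...), or a function `f(idx)` returning a log marginal
#'   likelihood.
#' @param p_max enumeration guard.
#' @return list with `models` (list of index vectors), `log_post`
#'   (unnormalised), `pmp` (normalised), and `pip` (length p).
#' @export
enumerate_posterior <- function(data, prior, engine = "la", p_max = 15L) {
  p <- data$p
  if (p > p_max)
    stop("p = ", p, " exceeds p_max = ", p_max, " for full enumeration")
  score <- if (is.function(engine)) {
    engine
  } else {
    if (is.character(engine)) engine <- marglik_engine(engine, data, prior)
    engine$log_marglik
  }
  n_mod <- 2L^p
  models <- vector("list", n_mod)
  log_post <- numeric(n_mod)
  for (m in seq_len(n_mod)) {
    bits <- as.logical(bitwAnd(m - 1L, bitwShiftL(1L, 0:(p - 1L))))
    idx <- which(bits)
    models[[m]] <- idx
    log_post[m] <- score(idx) + log_model_prior_size(length(idx), prior, p)
  }
  pmp <- exp(log_post - logsumexp(log_post))
  pmp <- pmp / sum(pmp)
  pip <- numeric(p)
  for (m in seq_len(n_mod)) pip[models[[m]]] <- pip[models[[m]]] + pmp[m]
  list(models = models, log_post = log_post, pmp = pmp, pip = pip)
}

#' Mean squared error of PIP estimates against a reference
#'
#' @param pip estimated PIPs.
#' @param reference gold-standard PIPs of the same length.
#' @return average over covariates of the squared error.
#' @export
pip_mse <- function(pip, reference) {
  stopifnot(length(pip) == length(reference))
  mean((pip - reference)^2)
}

#' Compare samplers by PIP accuracy against a gold standard
#'
#' Runs each candidate configuration for `n_iter` iterations (an
#' iteration-matched comparison; wall-time matching is hardware-dependent
#' and not used here) over `repetitions` seeds and reports the average PIP
#' MSE against `gold_pip`, plus the relative efficiency of each candidate
#' versus the first one (ratio of baseline MSE to candidate MSE, larger
#' is better).
#'
#' @param candidates named list of zero-argument functions, each returning a
#'   fitted object with a `pip` element (wrap [parni()] calls).
#' @param gold_pip reference PIP vector.
#' @param repetitions number of replicate runs per candidate (seeds
#'   `seed_base + 1:repetitions` are applied with [set.seed()]).
#' @param seed_base base seed.
#' @return data frame with candidate, seed, and MSE; relative efficiencies
#'   in `attr(, "relative_efficiency")`.
#' @export
benchmark_samplers <- function(candidates, gold_pip, repetitions = 3,
                               seed_base = 0) {
  stopifnot(length(names(candidates)) == length(candidates))
  rows <- list()
  for (nm in names(candidates)) {
    for (r in seq_len(repetitions)) {
      set.seed(seed_base + r)
      fit <- candidates[[nm]]()
      rows[[length(rows) + 1L]] <-
        data.frame(candidate = nm, seed = seed_base + r,
                   mse = pip_mse(fit$pip, gold_pip))
    }
  }
  out <- do.call(rbind, rows)
  avg <- tapply(out$mse, out$candidate, mean)
  attr(out, "average_mse") <- avg
  attr(out, "relative_efficiency") <- avg[[1]] / avg
  out
}
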