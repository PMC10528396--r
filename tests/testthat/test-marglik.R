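# Marginal-likelihood engines: MAP optimisation, LA, ALA, adaptive ALA, CPM.

logistic_fixture <- function(seed = 1, n = 60, p = 5) {
  set.seed(seed)
  supp <- if (p >= 4) c(1L, 4L) else 1L
  sim <- simulate_bvs(n = n, p = p, family = "logistic",
                      true_support = supp,
                      effect_sizes = rep_len(c(1.5, -1.5), length(supp)),
                      correlation = "independent", intercept = FALSE)
  sim$data
}

test_that("MAP estimate matches an independent BFGS optimiser", {
  pr <- bvs_prior(g = 2, sigma_alpha2 = 1, h = 0.3)
  for (seed in 1:3) {
    d <- logistic_fixture(seed, n = 80, p = 5)
    idx <- sort(sample(5, 2))
    fit <- map_estimate(idx, d, pr)
    J <- build_design(idx, d)
    v <- parni:::prior_var_diag(pr, 0, 2)
    nlp <- function(th) -parni:::log_post_theta(th, J, v, d)
    opt <- optim(c(0, 0), nlp, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_lt(max(abs(fit$theta - opt$par)), 1e-6)
    # gradient at the mode is numerically zero
    gr <- crossprod(J, parni:::score_eta(fit$eta, d)) - fit$theta / v
    expect_lt(max(abs(gr)), 1e-8)
  }
})

test_that("null-model LA is the exact log-likelihood at the empty model", {
  d <- logistic_fixture(2, n = 40, p = 4)
  pr <- bvs_prior(g = 1, h = 0.5)
  expect_equal(log_marglik_la(integer(0), d, pr)$log_value, -40 * log(2))
})

test_that("LA matches 1-D adaptive quadrature on single-covariate models", {
  d <- logistic_fixture(3, n = 30, p = 4)
  pr <- bvs_prior(g = 2, sigma_alpha2 = 1, h = 0.3)
  for (j in c(1L, 3L)) {
    la <- log_marglik_la(j, d, pr)$log_value
    expect_lt(abs(la - quadrature_marglik_1d(j, d, pr)), 0.05)
  }
})

test_that("ALA at the converged mode coincides with LA", {
  pr <- bvs_prior(g = 1.5, sigma_alpha2 = 1, h = 0.3)
  fams <- c("logistic", "cox", "weibull")
  for (f in fams) {
    sim <- make_enumerable_fixture(f, seed = 11, n = 80, p = 6)
    d <- sim$data
    for (r in 1:3) {
      idx <- sort(sample(6, sample(0:3, 1)))
      fit <- map_estimate(idx, d, pr)
      la <- log_marglik_la(idx, d, pr, fit = fit)$log_value
      ala <- log_marglik_ala(idx, d, pr, theta0 = fit$theta)$log_value
      expect_lt(abs(ala - la), 1e-8)
    }
  }
})

test_that("ALA at the origin equals the direct closed-form evaluation", {
  d <- logistic_fixture(4, n = 50, p = 4)
  pr <- bvs_prior(g = 2, sigma_alpha2 = 1, h = 0.3)
  idx <- c(1L, 2L)
  J <- build_design(idx, d)
  # direct route: y-tilde = y - 1/2 and W = I/4 at the origin
  ytilde <- d$y - 0.5
  H0 <- crossprod(J) / 4 + diag(1 / 2, 2)
  g0 <- drop(crossprod(J, ytilde))
  direct <- -50 * log(2) + sum(dnorm(c(0, 0), 0, sqrt(2), log = TRUE)) +
    log(2 * pi) - 0.5 * determinant(H0)$modulus[1] +
    0.5 * drop(crossprod(g0, solve(H0, g0)))
  expect_equal(log_marglik_ala(idx, d, pr)$log_value, direct,
               tolerance = 1e-10)
})

test_that("ALA is invariant to covariate ordering", {
  d <- logistic_fixture(5, n = 40, p = 5)
  pr <- bvs_prior(g = 1, h = 0.4)
  perm <- c(4L, 1L, 5L, 3L, 2L)
  d2 <- bvs_data(d$x[, perm], y = d$y, family = "logistic")
  # model {1, 3} in the original ordering is {2, 4} after permutation
  expect_equal(log_marglik_ala(c(1L, 3L), d, pr)$log_value,
               log_marglik_ala(c(2L, 4L), d2, pr)$log_value)
})

test_that("adaptive ALA is a fixed point at the mode and composes from 0", {
  d <- logistic_fixture(6, n = 60, p = 5)
  pr <- bvs_prior(g = 1, sigma_alpha2 = 1, h = 0.3)
  idx <- c(2L, 5L)
  fit <- map_estimate(idx, d, pr)
  la <- log_marglik_la(idx, d, pr, fit = fit)$log_value
  # eta-hat equal to the model's own MAP predictor reproduces LA
  expect_equal(log_marglik_adaptive_ala(idx, d, pr, fit$eta)$log_value, la,
               tolerance = 1e-8)
  # eta-hat = 0 projects to theta0 = 0; compare with composing the two
  # steps explicitly (one Newton step from the origin, then ALA there)
  J <- build_design(idx, d)
  v <- parni:::prior_var_diag(pr, 0, 2)
  pd <- parni:::post_derivs(numeric(2), J, v, d)
  theta1 <- numeric(2) + solve(pd$neg_hessian, pd$grad)
  expect_equal(log_marglik_adaptive_ala(idx, d, pr,
                                        numeric(d$n))$log_value,
               log_marglik_ala(idx, d, pr, theta0 = theta1)$log_value)
})

test_that("adaptive ALA improves on origin ALA for most models", {
  set.seed(7)
  sim <- simulate_bvs(n = 200, p = 10, family = "logistic",
                      true_support = c(1L, 2L, 3L),
                      effect_sizes = c(1.5, -1, 0.8),
                      correlation = "independent", intercept = FALSE)
  d <- sim$data
  pr <- bvs_prior(g = 1, h = 0.3)
  eta_hat <- map_estimate(c(1L, 2L, 3L), d, pr)$eta
  wins <- 0L
  n_models <- 30L
  for (r in seq_len(n_models)) {
    idx <- sort(sample(10, sample(1:5, 1)))
    la <- log_marglik_la(idx, d, pr)$log_value
    e_ad <- abs(log_marglik_adaptive_ala(idx, d, pr, eta_hat)$log_value - la)
    e_or <- abs(log_marglik_ala(idx, d, pr)$log_value - la)
    if (e_ad <= e_or + 1e-10) wins <- wins + 1L
  }
  expect_gte(wins / n_models, 0.9)
})

test_that("CPM with a single zero auxiliary sample recovers LA", {
  d <- logistic_fixture(8, n = 40, p = 4)
  pr <- bvs_prior(g = 1, h = 0.3)
  idx <- c(1L, 4L)
  la <- log_marglik_la(idx, d, pr)$log_value
  cpm <- log_marglik_cpm(idx, d, pr, u = matrix(0, 1, 2))$log_value
  expect_equal(cpm, la, tolerance = 1e-12)
})

test_that("CPM estimates centre on the quadrature marginal likelihood", {
  set.seed(9)
  d <- logistic_fixture(9, n = 30, p = 3)
  pr <- bvs_prior(g = 2, h = 0.3)
  truth <- exp(quadrature_marglik_1d(1L, d, pr))
  est <- replicate(80, exp(log_marglik_cpm(1L, d, pr, N = 32L)$log_value))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se + 1e-12)
})

test_that("marglik engines memoise and report modes", {
  d <- logistic_fixture(10, n = 40, p = 4)
  pr <- bvs_prior(g = 1, h = 0.3)
  eng <- marglik_engine("la", d, pr)
  v1 <- eng$log_marglik(c(1L, 2L))
  v2 <- eng$log_marglik(c(1L, 2L))
  expect_identical(v1, v2)
  expect_equal(v1, log_marglik_la(c(1L, 2L), d, pr)$log_value)
  me <- eng$mode_eta(c(1L, 2L))
  expect_equal(me, map_estimate(c(1L, 2L), d, pr)$eta)
  expect_null(marglik_engine("ala", d, pr)$mode_eta(c(1L)))
})
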