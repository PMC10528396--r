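# PARNI proposal machinery: neighbourhood draws, informed walk, acceptance,
# adaptation, determinism.

test_that("balancing function and Hamming distance behave", {
  expect_equal(balancing_gH(1), 1)
  expect_equal(balancing_gH(4), 1)
  expect_equal(balancing_gH(0.25), 0.25)
  expect_error(balancing_gH(-1))
  set.seed(1)
  x <- exp(runif(200, -8, 8))
  expect_lt(max(abs(balancing_gH(x) - x * balancing_gH(1 / x))), 1e-12)
  expect_equal(hamming(c(0, 0, 0), c(1, 0, 1)), 2)
  expect_equal(hamming(c(1, 1), c(1, 1)), 0)
  a <- rbinom(20, 1, 0.5); b <- rbinom(20, 1, 0.5)
  expect_equal(hamming(a, b), hamming(b, a))
  expect_error(hamming(c(0, 1), c(0, 1, 1)))
})

test_that("flip-set draws follow the A/D Bernoulli law", {
  set.seed(2)
  p <- 5
  gamma_bin <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  A <- c(0.9, 0.3, 0.9, 0.7, 0.1)
  D <- c(0.5, 0.9, 0.2, 0.9, 0.9)
  n_rep <- 2e4
  ks <- replicate(n_rep, sample_k(gamma_bin, A, D)$k)
  freq <- rowMeans(ks)
  expected <- ifelse(gamma_bin, D, A)
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_true(all(abs(freq - expected) < 3.5 * se))
  # E[p_k] = sum of the Bernoulli probabilities when A = D = eps
  eps <- 0.05
  pk <- replicate(5e3, sample_k(gamma_bin, rep(eps, p), rep(eps, p))$p_k)
  expect_lt(abs(mean(pk) - p * eps), 3 * sd(pk) / sqrt(5e3))
  # companion density matches simulation frequencies (chi-square GOF)
  keys <- apply(ks + 0L, 2, paste, collapse = "")
  tab <- table(keys)
  probs <- vapply(names(tab), function(kk) {
    kv <- as.integer(strsplit(kk, "")[[1]]) == 1L
    exp(parni:::log_k_density(kv, gamma_bin, A, D))
  }, numeric(1))
  observed_all <- c(as.vector(tab), max(0L, n_rep - sum(tab)))
  probs_all <- c(probs, max(0, 1 - sum(probs)))
  keep <- probs_all > 1e-12
  gof <- suppressWarnings(
    chisq.test(observed_all[keep], p = probs_all[keep], rescale.p = TRUE))
  expect_gt(gof$p.value, 1e-3)
})

test_that("the point-wise walk reports exact path probabilities", {
  # flat scores, zeta = 1/2: every flip fires with probability 1/2
  flat <- function(idx) 0
  p <- 4
  gamma_bin <- rep(FALSE, p)
  A <- rep(0.5, p); D <- rep(0.5, p)
  draw <- list(k = rep(TRUE, p), p_k = p, order = 1:4)
  set.seed(3)
  outs <- replicate(3000, {
    w <- parni:::pointwise_walk(integer(0), gamma_bin, draw, A, D, 0.5, flat)
    c(length(w$flipped), exp(w$log_q_forward), w$n_eval)
  })
  expect_equal(mean(outs[1, ]), p / 2, tolerance = 0.1)
  # with equal weights every realised path has probability (1/2)^p
  expect_true(all(abs(outs[2, ] - 0.5^p) < 1e-12))
  expect_true(all(outs[3, ] == 2 * p))
  # informative scores: empirical frequency of each outcome matches its
  # reported forward probability, and the probabilities sum to 1
  score <- function(idx) 0.8 * length(idx) - 0.3 * sum(idx)
  set.seed(4)
  res <- replicate(2e4, {
    w <- parni:::pointwise_walk(integer(0), gamma_bin, draw, A, D, 0.4,
                                score)
    c(key = parni:::gamma_key(w$idx), q = exp(w$log_q_forward))
  })
  keys <- res[1, ]
  qs <- as.numeric(res[2, ])
  tab <- table(keys) / length(keys)
  qmap <- tapply(qs, keys, function(z) z[1])
  expect_equal(sum(qmap), 1, tolerance = 1e-9)  # all 16 outcomes reachable
  for (kk in names(tab)) {
    se <- sqrt(qmap[[kk]] * (1 - qmap[[kk]]) / length(keys))
    expect_lt(abs(tab[[kk]] - qmap[[kk]]), 4 * se + 1e-4)
  }
})

test_that("empty flip-sets propose the current model with certainty", {
  draw <- list(k = rep(FALSE, 3), p_k = 0L, order = integer(0))
  w <- parni:::pointwise_walk(c(2L), c(FALSE, TRUE, FALSE), draw,
                              rep(0.1, 3), rep(0.1, 3), 0.5,
                              function(idx) stop("no evaluations expected"))
  expect_identical(w$idx, c(2L))
  expect_identical(w$log_q_forward, 0)
  expect_identical(w$log_q_reverse, 0)
  expect_identical(w$n_eval, 0L)
})

test_that("frozen-tuning PARNI satisfies detailed balance empirically", {
  set.seed(5)
  sim <- make_enumerable_fixture("logistic", seed = 5, n = 60, p = 4)
  d <- sim$data
  pr <- bvs_prior(g = 1, sigma_alpha2 = 1, h = 0.4)
  en <- enumerate_posterior(d, pr, "la")
  eng <- marglik_engine("la", d, pr)
  n_iter <- 6e4
  res <- parni:::run_parni_chain(d, pr, eng, eng, n_iter = n_iter,
                                 burnin = 0, freeze_adaptation = TRUE,
                                 zeta = 0.4, store_models = TRUE)
  # stationarity: empirical PMPs match enumeration
  freq <- model_freq(res$models)
  keys <- vapply(en$models, parni:::gamma_key, character(1))
  emp <- as.numeric(freq[keys])
  emp[is.na(emp)] <- 0
  expect_lt(max(abs(emp - en$pmp)), 0.02)
  # flow symmetry between the two top models
  top2 <- order(en$pmp, decreasing = TRUE)[1:2]
  k1 <- keys[top2[1]]; k2 <- keys[top2[2]]
  mk <- vapply(res$models, parni:::gamma_key, character(1))
  f12 <- mean(mk[-n_iter] == k1 & mk[-1] == k2)
  f21 <- mean(mk[-n_iter] == k2 & mk[-1] == k1)
  se <- sqrt((f12 + f21) / n_iter)
  expect_lt(abs(f12 - f21), 4 * se + 1e-4)
})

test_that("burn-in weights and A/D maps follow the adaptation schedule", {
  nb <- 100
  expect_equal(parni:::phi_weight(nb, nb), 0.5)
  expect_equal(parni:::phi_weight(nb + 4, nb), 0.25)
  expect_equal(parni:::phi_weight(nb - 3, nb), 0.75)
  expect_true(all(vapply(1:(nb - 1), parni:::phi_weight, numeric(1),
                         n_burn = nb) > 0.5))
  # at l = N_b + 1 the weight is exactly 1/2 and decays monotonically after
  after <- vapply(nb + 1:50, parni:::phi_weight, numeric(1), n_burn = nb)
  expect_true(all(diff(after) < 0) && all(after <= 0.5))
  eps <- 0.001
  ad <- parni:::pips_to_AD(0.5, eps)
  expect_equal(ad$A, 1 - eps)
  expect_equal(ad$D, 1 - eps)
  ad2 <- parni:::pips_to_AD(c(1e-9, 1 - 1e-9), eps)
  expect_equal(ad2$A, c(eps, 1 - eps))
  expect_equal(ad2$D, c(1 - eps, eps))
})

test_that("zeta adaptation has bounded diminishing steps and drifts down on rejects", {
  eps <- 0.001
  zeta <- 0.3
  path <- numeric(50)
  for (l in 1:50) {
    lgt_old <- qlogis(zeta)
    lgt <- lgt_old + l^(-0.7) * (0 - 0.234)   # all-reject stream
    expect_lte(abs(lgt - lgt_old), l^(-0.7))
    zeta <- min(max(plogis(lgt), eps), 1 - eps)
    path[l] <- zeta
  }
  expect_true(all(diff(path) <= 0))
})

test_that("eta-hat is the running mean of visited MAP linear predictors", {
  set.seed(6)
  sim <- make_enumerable_fixture("logistic", seed = 6, n = 50, p = 4)
  d <- sim$data
  pr <- bvs_prior(g = 1, h = 0.4)
  eng <- marglik_engine("la", d, pr)
  res <- parni:::run_parni_chain(d, pr, eng, eng, n_iter = 60, burnin = 20,
                                 store_models = TRUE)
  batch <- Reduce(`+`, lapply(res$models, function(m) {
    map_estimate(m, d, pr)$eta
  })) / length(res$models)
  expect_lt(max(abs(res$eta_hat - batch)), 1e-10)
})

test_that("a fixed seed reproduces the chain bit for bit", {
  sim <- make_enumerable_fixture("logistic", seed = 7, n = 50, p = 5)
  d <- sim$data
  run <- function() {
    set.seed(42)
    eng <- marglik_engine("cpm", d, bvs_prior(g = 1, h = 0.3))
    prop <- marglik_engine("adaptive_ala", d, bvs_prior(g = 1, h = 0.3))
    parni:::run_parni_chain(d, bvs_prior(g = 1, h = 0.3), prop, eng,
                            n_iter = 150, burnin = 50)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$pip, r2$pip)
  expect_identical(r1$log_post, r2$log_post)
  expect_identical(r1$accepted, r2$accepted)
})

test_that("diminishing adaptation: A moves vanish along the run", {
  set.seed(8)
  sim <- make_enumerable_fixture("logistic", seed = 8, n = 60, p = 5)
  d <- sim$data
  pr <- bvs_prior(g = 1, h = 0.3)
  pw <- warm_start_pips(integer(0), d, pr)
  pw <- pmin(pmax(pw, 0.001), 0.999)
  # reconstruct the A-path from a stored chain and bound the increments
  eng <- marglik_engine("la", d, pr)
  res <- parni:::run_parni_chain(d, pr, eng, eng, n_iter = 3000,
                                 burnin = 500, store_models = TRUE)
  gb <- t(vapply(res$models, function(m) {
    z <- logical(d$p); z[m] <- TRUE; z
  }, logical(d$p)))
  counts <- apply(gb, 2, cumsum)
  iters <- seq_len(nrow(gb))
  deltas <- vapply(seq(1000, 2990, by = 10), function(l) {
    pi1 <- parni:::phi_weight(l, 500) * pw +
      (1 - parni:::phi_weight(l, 500)) * counts[l, ] / l
    pi2 <- parni:::phi_weight(l + 1, 500) * pw +
      (1 - parni:::phi_weight(l + 1, 500)) * counts[l + 1, ] / (l + 1)
    max(abs(parni:::pips_to_AD(pi2, 0.001)$A -
              parni:::pips_to_AD(pi1, 0.001)$A))
  }, numeric(1))
  expect_lt(max(tail(deltas, 50)), max(head(deltas, 50)) + 1e-6)
  expect_lt(tail(deltas, 1), 0.01)
})

test_that("neighbourhoods contain 2^p_k models", {
  # enumerate N(gamma, k) from its definition for p_k <= 4
  p <- 6
  gamma_bin <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  for (pk in 0:4) {
    kpos <- sample(p, pk)
    k <- logical(p); k[kpos] <- TRUE
    # models agreeing with gamma wherever k_j = 0
    count <- 0L
    for (m in 0:(2^p - 1)) {
      bits <- as.logical(bitwAnd(m, 2^(0:(p - 1))))
      if (all(bits[!k] == gamma_bin[!k])) count <- count + 1L
    }
    expect_equal(count, 2^pk)
  }
})
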