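make_toy_switching <- function(seed = 101, M = 2, d = 2, C = 10,
                               delta = 0.01, dwell = 0.3) {
  sample_switching_system(sim_config(d = d, C = C, delta = delta, M = M,
                                     dwell_time = dwell), seed = seed)
}

test_that("predictive likelihood matches closed forms and dense quadrature", {
  # beta = 0: exactly the Poisson pmf at rate e^alpha
  p0 <- plds_params(A = matrix(0.9), Q = matrix(0.01), mu0 = 0,
                    Lambda0 = matrix(1), alpha = log(c(0.3, 0.05)),
                    beta = matrix(0, 2, 1), delta = 0.01)
  pred <- gaussian_belief(0.4, matrix(0.3), "predicted")
  got <- switching_predictive_loglik(pred, c(1, 0), p0)
  expect_equal(got, sum(dpois(c(1, 0), c(0.3, 0.05), log = TRUE)),
               tolerance = 1e-10)
  # vanishing covariance: plug-in log-likelihood at the mean
  p1 <- plds_params(A = matrix(0.9), Q = matrix(0.01), mu0 = 0,
                    Lambda0 = matrix(1), alpha = log(0.2), beta = matrix(0.9),
                    delta = 0.01)
  got1 <- switching_predictive_loglik(gaussian_belief(0.5, matrix(1e-14),
                                                      "predicted"), 1, p1)
  expect_equal(got1, plds_log_likelihood(1, 0.5, p1), tolerance = 1e-6)
  # dense quadrature of int P(n | x) N(x) dx
  dens <- function(x) sapply(x, function(xi)
    dpois(1, exp(log(0.2) + 0.9 * xi))) * dnorm(x, 0.2, sqrt(0.25))
  truth <- log(integrate(dens, -6, 6, rel.tol = 1e-10)$value)
  got2 <- switching_predictive_loglik(gaussian_belief(0.2, matrix(0.25),
                                                      "predicted"), 1, p1)
  expect_lt(abs(got2 - truth), 0.01 * abs(truth))
})

test_that("one-regime switching runs reduce to the stationary filter and smoother", {
  sys <- sample_stationary_system(sim_config(d = 2, C = 8), seed = 111)
  sim <- simulate_trajectory(sys, 120, seed = 112)
  one <- switching_plds_params(list(sys), matrix(1, 1, 1), 1)
  sw <- run_switching_filter(sim$spikes, one, method = "pcf")
  st <- run_filter(sim$spikes, sys, method = "pcf")
  expect_equal(sw$xf[[1]], st$xf, tolerance = 1e-10)
  expect_true(all(sw$w_filt == 1))
  swm <- run_switching_smoother(sw, one)
  stm <- rts_smooth(st, sys$A, sys$Q, sys$mu0, sys$Lambda0)
  expect_equal(swm$xs[[1]], stm$xs, tolerance = 1e-9)
  expect_equal(swm$Ps[[1]], stm$Ps, tolerance = 1e-9)
  expect_equal(swm$cross[[1]], stm$cross, tolerance = 1e-9)
  expect_equal(swm$x_prev[[1]][, 1], stm$x0, tolerance = 1e-9)
})

test_that("identical regimes leave the regime posterior at its Markov prediction", {
  sys <- sample_stationary_system(sim_config(d = 2, C = 8), seed = 115)
  sim <- simulate_trajectory(sys, 60, seed = 116)
  Phi <- matrix(c(0.97, 0.03, 0.05, 0.95), 2, 2)   # column-stochastic
  params <- switching_plds_params(list(sys, sys), Phi, c(0.7, 0.3))
  tr <- run_switching_filter(sim$spikes, params, method = "pcf")
  # identical likelihoods cancel: filtered probs follow the chain prediction
  # step 1 keeps the initial distribution; afterwards the chain prediction
  w <- c(0.7, 0.3)
  expect_equal(tr$w_filt[, 1], w, tolerance = 1e-9)
  for (t in 2:60) {
    w <- as.vector(Phi %*% w)
    expect_equal(tr$w_filt[, t], w, tolerance = 1e-9)
  }
})

test_that("regime probabilities normalize and permuting labels permutes outputs", {
  sys <- make_toy_switching(seed = 121, M = 3, dwell = 0.2)
  sim <- simulate_trajectory(sys, 150, seed = 122)
  tr <- run_switching_filter(sim$spikes, sys, method = "pcf")
  expect_equal(colSums(tr$w_filt), rep(1, 150), tolerance = 1e-10)
  sm <- run_switching_smoother(tr, sys)
  expect_equal(colSums(sm$Ws), rep(1, 150), tolerance = 1e-8)
  # marginal consistency of pairwise probabilities
  for (t in 2:150) {
    expect_equal(colSums(sm$pairwise[, , t]), sm$Ws[, t - 1], tolerance = 1e-8)
    expect_equal(rowSums(sm$pairwise[, , t]), sm$Ws[, t], tolerance = 1e-8)
  }
  # label permutation equivariance
  perm <- c(2, 3, 1)
  sys_p <- switching_plds_params(sys$regimes[perm],
                                 sys$Phi[perm, perm], sys$pi[perm])
  tr_p <- run_switching_filter(sim$spikes, sys_p, method = "pcf")
  expect_equal(tr_p$w_filt, tr$w_filt[perm, ], tolerance = 1e-8)
  expect_equal(tr_p$xf[[1]], tr$xf[[perm[1]]], tolerance = 1e-7)
})

test_that("a pinned chain reproduces the stationary filter of that regime", {
  sys <- make_toy_switching(seed = 131, M = 2)
  pinned <- switching_plds_params(sys$regimes, diag(2), c(0, 1))
  sim <- simulate_trajectory(sys$regimes[[2]], 100, seed = 132)
  sw <- run_switching_filter(sim$spikes, pinned, method = "pcf")
  st <- run_filter(sim$spikes, sys$regimes[[2]], method = "pcf")
  expect_equal(sw$w_filt[2, ], rep(1, 100))
  expect_equal(sw$xf[[2]], st$xf, tolerance = 1e-9)
})

test_that("compiled and reference switching paths agree", {
  sys <- make_toy_switching(seed = 141, M = 2)
  sim <- simulate_trajectory(sys, 120, seed = 142)
  for (method in c("pcf", "ppf")) {
    a <- run_switching_filter(sim$spikes, sys, method = method,
                              use_cpp = FALSE, spike_probs = TRUE)
    b <- run_switching_filter(sim$spikes, sys, method = method,
                              use_cpp = TRUE, spike_probs = TRUE)
    expect_equal(a$w_filt, b$w_filt, tolerance = 1e-8)
    expect_equal(a$xf[[1]], b$xf[[1]], tolerance = 1e-7)
    expect_equal(a$ell, b$ell, tolerance = 1e-7)
    expect_equal(a$spike_prob, b$spike_prob, tolerance = 1e-8)
    sa <- run_switching_smoother(a, sys, use_cpp = FALSE)
    sb <- run_switching_smoother(b, sys, use_cpp = TRUE)
    expect_equal(sa$Ws, sb$Ws, tolerance = 1e-8)
    expect_equal(sa$pairwise, sb$pairwise, tolerance = 1e-8)
    expect_equal(sa$xs[[2]], sb$xs[[2]], tolerance = 1e-6)
    expect_equal(sa$cross[[1]], sb$cross[[1]], tolerance = 1e-6)
    expect_equal(sa$merged_mean, sb$merged_mean, tolerance = 1e-7)
  }
})

test_that("switching smoother matches exhaustive regime-sequence enumeration", {
  # 2-regime linear-Gaussian systems, T = 6: all 64 sequences enumerated.
  # Representative system: damped, moderately separated regimes with
  # same-sign tuning, as in the simulated study systems.
  err <- enumeration_error(seed = 1,
                           As = list(matrix(0.95), matrix(0.85)),
                           Qs = list(matrix(0.05), matrix(0.08)),
                           Hs = list(matrix(c(1, 0.6), 2, 1),
                                     matrix(c(0.6, 1), 2, 1)),
                           Rs = list(diag(0.25, 2), diag(0.25, 2)))
  expect_lt(err, 0.02)
  # adversarial stress case (sign-flipped emissions, strongly different
  # dynamics): the single-Gaussian-per-regime smoother is expected to be
  # coarser here, but must stay within 5%
  err2 <- enumeration_error(seed = 151,
                            As = list(matrix(0.95), matrix(0.4)),
                            Qs = list(matrix(0.05), matrix(0.25)),
                            Hs = list(matrix(c(1, 0.5), 2, 1),
                                      matrix(c(-0.8, 1.2), 2, 1)),
                            Rs = list(diag(0.3, 2), diag(0.3, 2)),
                            L0 = matrix(0.5))
  expect_lt(err2, 0.05)
})

test_that("regime decoding takes the argmax with low-index tie-breaks", {
  probs <- rbind(c(0.2, 0.5, 1 / 3), c(0.8, 0.5, 1 / 3), c(0, 0, 1 / 3))
  expect_equal(decode_regimes(probs), c(2, 1, 1))
  # hand-computed argmax on a 5-step trace
  p5 <- rbind(c(.1, .6, .3, .25, .9), c(.9, .4, .7, .75, .1))
  expect_equal(decode_regimes(p5), c(2, 1, 2, 2, 1))
})

test_that("filtered regime accuracy beats chance on well-separated systems", {
  set.seed(161)
  wins <- 0
  n_seeds <- 20
  accs <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sys <- make_toy_switching(seed = 200 + k, M = 3, C = 15, dwell = 0.4)
    sim <- simulate_trajectory(sys, 400, seed = 300 + k)
    tr <- run_switching_filter(sim$spikes, sys, method = "pcf")
    accs[k] <- regime_accuracy(sim$regimes, decode_regimes(tr), 3)$acc
  }
  # one-sided binomial-style check: all seeds above chance is overwhelming
  # evidence; require at least 18/20 (p << 0.01 under the null)
  expect_gte(sum(accs > 1 / 3), 18)
})
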