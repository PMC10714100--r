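lg_spikes <- function(Y) structure(list(counts = Y, delta = 1,
                                        C = nrow(Y), T = ncol(Y)),
                                   class = "spike_data")

test_that("linear-Gaussian E-step sufficient statistics equal the Kalman smoother's", {
  set.seed(201)
  d <- 2; C <- 4; T <- 40
  A <- matrix(c(0.85, 0.1, -0.2, 0.7), 2, 2); Q <- diag(c(0.04, 0.08))
  mu0 <- c(0.2, -0.1); L0 <- diag(0.3, 2)
  H <- matrix(rnorm(C * d), C, d); b <- rnorm(C); R <- diag(0.3, C)
  Y <- matrix(rnorm(C * T), C, T)
  params <- plds_params(A, Q, mu0, L0, rep(0, C), matrix(0, C, d), 1)
  tr <- run_filter(lg_spikes(Y), params, method = "pcf",
                   moments = gaussian_moments(H, b, R))
  sm <- rts_smooth(tr, A, Q, mu0, L0, use_cpp = FALSE)
  kf <- oracle_kalman_filter(Y, A, Q, mu0, L0, H, b, R)
  ks <- oracle_kalman_smoother(kf, A, Q, mu0, L0)
  expect_equal(sm$xs, ks$xs, tolerance = 1e-8)
  expect_equal(sm$cross, ks$cross, tolerance = 1e-8)
})

test_that("dynamics M-step reproduces classical LDS-EM updates and recovers noiseless dynamics", {
  set.seed(203)
  d <- 2; C <- 4; T <- 30
  A <- matrix(c(0.9, 0.05, -0.1, 0.8), 2, 2); Q <- diag(c(0.05, 0.03))
  mu0 <- c(0, 0); L0 <- diag(0.4, 2)
  H <- matrix(rnorm(C * d), C, d); b <- rep(0, C); R <- diag(0.2, C)
  Y <- matrix(rnorm(C * T), C, T)
  params <- plds_params(A, Q, mu0, L0, rep(0, C), matrix(0, C, d), 1)
  tr <- run_filter(lg_spikes(Y), params, method = "pcf",
                   moments = gaussian_moments(H, b, R))
  sm <- rts_smooth(tr, A, Q, mu0, L0, use_cpp = FALSE)
  stats <- structure(list(Ex = sm$xs, Vx = sm$Ps, cross = sm$cross,
                          x0 = sm$x0, P0 = sm$P0, T = T, d = d),
                     class = "suff_stats")
  got <- mstep_dynamics(stats)
  kf <- oracle_kalman_filter(Y, A, Q, mu0, L0, H, b, R)
  oracle <- oracle_lds_em_dynamics(oracle_kalman_smoother(kf, A, Q, mu0, L0), T)
  expect_equal(got$A, oracle$A, tolerance = 1e-8)
  expect_equal(got$Q, oracle$Q, tolerance = 1e-8)
  expect_equal(got$mu0, oracle$mu0, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(got$Lambda0, oracle$Lambda0, tolerance = 1e-8)

  # noiseless known states recover A exactly
  A0 <- matrix(c(0.7, 0.2, -0.3, 0.9), 2, 2)
  X <- matrix(0, 2, 50); X[, 1] <- c(1, -1)
  for (t in 2:50) X[, t] <- A0 %*% X[, t - 1]
  zeroV <- array(0, c(2, 2, 49))
  cross <- array(0, c(2, 2, 49))
  for (t in 2:50) cross[, , t - 1] <- tcrossprod(X[, t], X[, t - 1])
  known <- structure(list(Ex = X[, 2:50], Vx = zeroV, cross = cross,
                          x0 = X[, 1], P0 = matrix(0, 2, 2), T = 49, d = 2),
                     class = "suff_stats")
  got2 <- mstep_dynamics(known)
  expect_equal(got2$A, A0, tolerance = 1e-9)
  expect_equal(got2$Q, matrix(0, 2, 2), tolerance = 1e-9)
})

test_that("observation M-step has the closed-form baseline and matches a Poisson GLM at zero covariance", {
  set.seed(207)
  d <- 2; C <- 6; T <- 500
  m <- matrix(rnorm(d * T, sd = 0.7), d, T)
  V0 <- array(0, c(d, d, T))
  counts <- matrix(rpois(C * T, 0.3), C, T)
  # beta pinned at 0 by zero moments in a d-dim sense: closed-form alpha is
  # log of the weighted mean count when m = 0
  m0 <- matrix(0, d, T)
  out0 <- mstep_observation(counts, m0, V0, alpha0 = rep(log(0.3), C),
                            beta0 = matrix(0, C, d))
  expect_equal(out0$alpha, log(rowMeans(counts)), tolerance = 1e-6)
  # zero covariance reduces to a standard Poisson GLM fit per neuron
  out <- mstep_observation(counts, m, V0, alpha0 = rep(log(0.3), C),
                           beta0 = matrix(0, C, d))
  for (i in 1:C) {
    ref <- glm(counts[i, ] ~ t(m), family = poisson())
    expect_equal(unname(c(out$alpha[i], out$beta[i, ])),
                 unname(coef(ref)), tolerance = 1e-6)
  }
})

test_that("observation objective is non-decreasing across Newton iterations", {
  set.seed(209)
  obj <- function(th, n, m, Smat, w) {
    d <- nrow(m)
    u <- th[1] + as.vector(crossprod(m, th[-1]))
    Sb <- matrix(0, d, ncol(m))
    for (l in 1:d) Sb <- Sb + Smat[((l - 1) * d + 1):(l * d), , drop = FALSE] * th[-1][l]
    v <- 0.5 * colSums(Sb * th[-1])
    sum(w * (n * u - exp(pmin(u + v, 30))))
  }
  for (rep in 1:50) {
    d <- sample(1:3, 1); T <- 60
    m <- matrix(rnorm(d * T, sd = 0.5), d, T)
    V <- array(0, c(d, d, T))
    for (t in 1:T) V[, , t] <- rand_psd(d, 0.05)
    w <- runif(T, 0.2, 1)
    n <- rpois(T, 0.4)
    a0 <- rnorm(1, log(0.4), 0.3); b0 <- rnorm(d, sd = 0.2)
    Smat <- matrix(V, d * d, T)
    before <- obj(c(a0, b0), n, m, Smat, w)
    fit <- mstep_observation(matrix(n, 1), m, V, w, a0, matrix(b0, 1))
    after <- obj(c(fit$alpha, fit$beta[1, ]), n, m, Smat, w)
    expect_gte(after, before - 1e-10)
  }
})

test_that("regime-chain M-step matches the closed-form HMM update", {
  set.seed(211)
  M <- 3; T <- 40
  pairwise <- array(0, c(M, M, T))
  Ws <- matrix(0, M, T)
  Ws[, 1] <- c(0.5, 0.3, 0.2)
  for (t in 2:T) {
    raw <- matrix(runif(M * M), M, M)
    raw <- raw * rep(Ws[, t - 1] / colSums(raw), each = M)  # consistent slices
    pairwise[, , t] <- raw
    Ws[, t] <- rowSums(raw)
  }
  got <- mstep_regime_chain(Ws, pairwise)
  for (i in 1:M) {
    num <- sapply(1:M, function(j) sum(pairwise[j, i, 2:T]))
    expect_equal(got$Phi[, i], num / sum(num), tolerance = 1e-10)
  }
  expect_equal(got$pi, Ws[, 1], tolerance = 1e-12)
  expect_equal(colSums(got$Phi), rep(1, M), tolerance = 1e-12)
  # deterministic alternation: off-diagonal 1
  alt <- array(0, c(2, 2, 4))
  Wa <- matrix(0.0, 2, 4); Wa[, 1] <- c(1, 0)
  alt[2, 1, 2] <- 1; Wa[, 2] <- c(0, 1)
  alt[1, 2, 3] <- 1; Wa[, 3] <- c(1, 0)
  alt[2, 1, 4] <- 1; Wa[, 4] <- c(0, 1)
  got2 <- mstep_regime_chain(Wa, alt)
  expect_equal(got2$Phi[2, 1], 1)
  expect_equal(got2$Phi[1, 2], 1)
})

test_that("the M-step never decreases the expected complete-data objective", {
  set.seed(213)
  sys <- sample_stationary_system(sim_config(d = 2, C = 10), seed = 214)
  sim <- simulate_trajectory(sys, 400, seed = 215)
  # start from a deliberately wrong parameter guess
  params <- pcfilter:::.init_stationary(sim$spikes, 2, seed = 216)
  for (it in 1:3) {
    st <- estep_stationary(params, sim$spikes, "pcf")
    before <- expected_complete_loglik(params, st, sim$spikes)
    dyn <- mstep_dynamics(st)
    obs <- mstep_observation(sim$spikes$counts, st$Ex, st$Vx,
                             alpha0 = params$alpha, beta0 = params$beta)
    params <- plds_params(dyn$A, dyn$Q, dyn$mu0, dyn$Lambda0,
                          obs$alpha, obs$beta, sim$spikes$delta)
    after <- expected_complete_loglik(params, st, sim$spikes)
    expect_gte(after, before - 1e-6 * abs(before))
  }
})

test_that("global Laplace agrees with filter-smoother moments at high rates", {
  set.seed(217)
  d <- 2
  p <- plds_params(A = diag(0.9, d), Q = diag(0.02, d), mu0 = rep(0, d),
                   Lambda0 = diag(0.1, d), alpha = rep(log(5), 8),
                   beta = matrix(rnorm(8 * d, sd = 0.3), 8, d), delta = 1)
  sim <- simulate_trajectory(p, 150, seed = 218)
  st_lap <- estep_stationary(p, sim$spikes, "global_laplace")
  st_pcf <- estep_stationary(p, sim$spikes, "pcf")
  sd_post <- mean(sqrt(st_pcf$Vx[1, 1, ]))
  expect_lt(mean(abs(st_lap$Ex - st_pcf$Ex)), 0.1 * sd_post)
  # sampling mode agrees with the deterministic moments
  lap_det <- global_laplace(sim$spikes, p)
  set.seed(219)
  lap_mc <- global_laplace(sim$spikes, p, sample = 4000)
  expect_lt(mean(abs(lap_det$xs - lap_mc$xs)), 0.05 * sd_post)
  expect_equal(mean(abs(lap_det$Ps - lap_mc$Ps)), 0, tolerance = 0.01)
})

test_that("EM runs are seeded, deterministic, and respect the iteration budget", {
  sys <- sample_stationary_system(sim_config(d = 2, C = 10), seed = 221)
  sim <- simulate_trajectory(sys, 300, seed = 222)
  f0 <- fit_plds_em(sim$spikes, d = 2, method = "pcf", iterations = 0, seed = 7)
  init <- pcfilter:::.init_stationary(sim$spikes, 2, seed = 7)
  expect_equal(f0$params$A, init$A)
  expect_equal(f0$params$beta, init$beta)
  a <- fit_plds_em(sim$spikes, d = 2, method = "pcf", iterations = 3, seed = 7)
  b <- fit_plds_em(sim$spikes, d = 2, method = "pcf", iterations = 3, seed = 7)
  expect_identical(a$params, b$params)
  expect_equal(nrow(a$diagnostics), 3)
})

test_that("stationary EM recovers eigenvalues on a small system", {
  sys <- sample_stationary_system(sim_config(d = 2, C = 20), seed = 223)
  sim <- simulate_trajectory(sys, 6000, seed = 224)
  fit <- fit_plds_em(sim$spikes, d = 2, method = "pcf", iterations = 30,
                     seed = 225)
  e <- eigenvalue_error(eigen(fit$params$A)$values, eigen(sys$A)$values)
  expect_lt(e, 0.1)
})

test_that("single-regime switch EM equals stationary EM", {
  sys <- sample_stationary_system(sim_config(d = 2, C = 8), seed = 227)
  sim <- simulate_trajectory(sys, 200, seed = 228)
  init_st <- pcfilter:::.init_stationary(sim$spikes, 2, seed = 9)
  init_sw <- switching_plds_params(list(init_st), matrix(1, 1, 1), 1)
  fs <- fit_plds_em(sim$spikes, d = 2, method = "pcf", iterations = 3,
                    init = init_st)
  fw <- fit_switching_em(sim$spikes, d = 2, M = 1, method = "spcf",
                         iterations = 3, init = init_sw)
  expect_equal(fw$params$regimes[[1]]$A, fs$params$A, tolerance = 1e-7)
  expect_equal(fw$params$regimes[[1]]$alpha, fs$params$alpha, tolerance = 1e-6)
  expect_equal(fw$params$regimes[[1]]$beta, fs$params$beta, tolerance = 1e-6)
})

test_that("switch EM is label-permutation invariant at the initialization", {
  sys <- sample_switching_system(sim_config(d = 2, C = 8, delta = 0.01, M = 2,
                                            dwell_time = 0.5), seed = 229)
  sim <- simulate_trajectory(sys, 300, seed = 230)
  init <- pcfilter:::.init_switching(sim$spikes, 2, 2, seed = 11)
  perm <- c(2, 1)
  init_p <- switching_plds_params(init$regimes[perm], init$Phi[perm, perm],
                                  init$pi[perm])
  f1 <- fit_switching_em(sim$spikes, d = 2, M = 2, method = "spcf",
                         iterations = 3, init = init)
  f2 <- fit_switching_em(sim$spikes, d = 2, M = 2, method = "spcf",
                         iterations = 3, init = init_p)
  expect_equal(f2$params$regimes[[1]]$A, f1$params$regimes[[2]]$A,
               tolerance = 1e-6)
  expect_equal(f2$params$Phi, f1$params$Phi[perm, perm], tolerance = 1e-6)
})
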