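## Ground-truth system generation and trajectory simulation.
##
## Systems are drawn the way the calibrated defaults describe: stable
## oscillatory dynamics with eigenvalues given by decay half-lives and
## oscillation frequencies, state-noise eigenvalues in a fixed band, and
## encoding parameters set from base and maximum firing rates.

#' Simulation configuration
#'
#' Defaults correspond to the calibrated simulation conditions: `d = 8`
#' latent dimensions, `C = 60` neurons, 2 ms bins, eigenvalue decay
#' half-lives in \[13, 277\] ms (moduli roughly \[0.9, 0.995\] at 2 ms),
#' oscillation frequencies in \[0.8, 5\] Hz, state-noise eigenvalues in
#' \[0.01, 0.04\], base firing rates in \[3, 5\] Hz, maximum firing rates in
#' \[50, 70\] Hz, and for switching systems `M = 3` regimes with a 2 s dwell
#' time and eigenvector transient control 2.4.
#'
#' @param d latent dimension (even, so eigenvalues pair into conjugates).
#' @param C number of neurons.
#' @param delta bin width, seconds.
#' @param half_life_range decay half-life range of the dynamics eigenvalues,
#'   seconds.
#' @param freq_range oscillation frequency range, Hz.
#' @param q_eig_range eigenvalue range of the state noise covariance `Q`.
#' @param base_rate_range baseline firing rate range at `x = 0`, Hz.
#' @param max_rate_range firing rate reached two latent standard deviations
#'   along each neuron's encoding direction, Hz.
#' @param M number of regimes (switching systems).
#' @param dwell_time expected regime dwell time, seconds.
#' @param transient_control bound on the condition number of the dynamics
#'   eigenvector matrix for switching regimes, limiting non-normal transient
#'   growth.
#' @return a `sim_config` list.
#' @export
sim_config <- function(d = 8, C = 60, delta = 0.002,
                       half_life_range = c(0.013, 0.277),
                       freq_range = c(0.8, 5),
                       q_eig_range = c(0.01, 0.04),
                       base_rate_range = c(3, 5),
                       max_rate_range = c(50, 70),
                       M = 3, dwell_time = 2,
                       transient_control = 2.4) {
  chk <- function(r) length(r) == 2 && all(r > 0) && r[1] <= r[2]
  stopifnot(d >= 1, C >= 1, delta > 0, chk(half_life_range), chk(freq_range),
            chk(q_eig_range), chk(base_rate_range), chk(max_rate_range),
            M >= 1, dwell_time > delta, transient_control >= 1)
  structure(as.list(environment())[c("d", "C", "delta", "half_life_range",
                                     "freq_range", "q_eig_range",
                                     "base_rate_range", "max_rate_range",
                                     "M", "dwell_time", "transient_control")],
            class = "sim_config")
}

#' Sample stable complex-conjugate eigenvalue pairs for the dynamics matrix
#'
#' Moduli come from decay half-lives (modulus `2^(-delta / t_half)` with
#' `t_half` uniform on `half_life_range`); angles from oscillation
#' frequencies (`theta = 2 pi delta f` with `f` uniform on `freq_range`).
#'
#' @param config [sim_config()]; `config$d` must be even.
#' @return complex vector of length `d` (conjugate pairs interleaved), all
#'   with modulus < 1.
#' @export
sample_eigenvalues <- function(config) {
  d <- config$d
  if (d %% 2 != 0) stop("d must be even: eigenvalues come in conjugate pairs")
  half <- d / 2
  thalf <- stats::runif(half, config$half_life_range[1], config$half_life_range[2])
  f <- stats::runif(half, config$freq_range[1], config$freq_range[2])
  r <- 2^(-config$delta / thalf)
  th <- 2 * pi * config$delta * f
  ev <- complex(modulus = rep(r, each = 2),
                argument = as.vector(rbind(th, -th)))
  ev
}

# real block-diagonal rotation-scaling realization of conjugate pairs
.block_rotation <- function(ev) {
  half <- length(ev) / 2
  d <- length(ev)
  B <- matrix(0, d, d)
  for (i in seq_len(half)) {
    r <- Mod(ev[2 * i - 1]); th <- abs(Arg(ev[2 * i - 1]))
    idx <- (2 * i - 1):(2 * i)
    B[idx, idx] <- r * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  }
  B
}

# Haar-ish random orthogonal matrix via QR of a Gaussian matrix
.rand_orth <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  Qm <- qr.Q(qrd)
  Qm %*% diag(sign(diag(qr.R(qrd))), d)
}

# random invertible conjugating map with condition number <= kappa,
# built as U1 diag(s) U2' with singular values uniform on [1, kappa]
.rand_conjugator <- function(d, kappa) {
  s <- stats::runif(d, 1, kappa)
  .rand_orth(d) %*% (s * t(.rand_orth(d)))
}

.rand_psd <- function(d, eig_range) {
  vals <- stats::runif(d, eig_range[1], eig_range[2])
  U <- .rand_orth(d)
  symmetrize(U %*% (vals * t(U)))
}

# encoding parameters: alpha from the base rate at x = 0; |beta| chosen so the
# rate reaches the max rate two latent standard deviations along the encoding
# direction under the stationary latent covariance Sinf
.sample_encoding <- function(config, Sinf) {
  C <- config$C; d <- config$d
  base <- stats::runif(C, config$base_rate_range[1], config$base_rate_range[2])
  rmax <- stats::runif(C, config$max_rate_range[1], config$max_rate_range[2])
  alpha <- log(base * config$delta)
  U <- matrix(stats::rnorm(C * d), C, d)
  U <- U / sqrt(rowSums(U^2))
  sd_dir <- sqrt(rowSums((U %*% Sinf) * U))   # sd of u' x per neuron
  mag <- log(rmax / base) / (2 * sd_dir)
  list(alpha = alpha, beta = U * mag)
}

#' Draw a random stationary Poisson-LDS ground-truth system
#'
#' The dynamics matrix realizes sampled conjugate eigenvalue pairs as 2x2
#' rotation-scaling blocks conjugated by a random orthogonal matrix; `Q` has
#' eigenvalues uniform on `q_eig_range` with random orthogonal eigenvectors;
#' the initial distribution is the stationary one (`mu0 = 0`, `Lambda0`
#' solving the discrete Lyapunov equation).
#'
#' @param config [sim_config()].
#' @param seed optional integer seed for reproducibility.
#' @return [plds_params()].
#' @export
sample_stationary_system <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- sample_eigenvalues(config)
  U <- .rand_orth(config$d)
  A <- U %*% .block_rotation(ev) %*% t(U)
  Q <- .rand_psd(config$d, config$q_eig_range)
  Sinf <- dlyap(A, Q)
  enc <- .sample_encoding(config, Sinf)
  plds_params(A = A, Q = Q, mu0 = rep(0, config$d), Lambda0 = Sinf,
              alpha = enc$alpha, beta = enc$beta, delta = config$delta)
}

#' Draw a random switching Poisson-LDS ground-truth system
#'
#' Per-regime dynamics are sampled as in the stationary case but conjugated
#' by a random invertible map whose condition number is bounded by
#' `transient_control`, so regimes differ in their eigenvector geometry while
#' transient growth stays bounded. The regime chain has
#' `Phi[j, j] = 1 - delta / dwell_time` with the switching mass split equally
#' among the other regimes, and a uniform initial distribution.
#'
#' @inheritParams sample_stationary_system
#' @param shared_observation if `TRUE`, all regimes share one draw of the
#'   observation parameters (`alpha`, `beta`), so switches affect dynamics
#'   only.
#' @return [switching_plds_params()].
#' @export
sample_switching_system <- function(config, seed = NULL,
                                    shared_observation = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$M
  p_stay <- 1 - config$delta / config$dwell_time
  Phi <- matrix((1 - p_stay) / max(M - 1, 1), M, M)
  diag(Phi) <- if (M == 1) 1 else p_stay
  shared_enc <- NULL
  regimes <- lapply(seq_len(M), function(j) {
    ev <- sample_eigenvalues(config)
    V <- .rand_conjugator(config$d, config$transient_control)
    A <- V %*% .block_rotation(ev) %*% solve(V)
    Q <- .rand_psd(config$d, config$q_eig_range)
    Sinf <- dlyap(A, Q)
    enc <- if (shared_observation && !is.null(shared_enc)) shared_enc else
      .sample_encoding(config, Sinf)
    if (shared_observation && is.null(shared_enc)) shared_enc <<- enc
    plds_params(A = A, Q = Q, mu0 = rep(0, config$d), Lambda0 = Sinf,
                alpha = enc$alpha, beta = enc$beta, delta = config$delta)
  })
  switching_plds_params(regimes, Phi, rep(1 / M, M))
}

#' Simulate latent, regime and spike trajectories
#'
#' For switching parameters the regime sequence is drawn first from the
#' Markov chain, then latents from the regime-indexed linear-Gaussian
#' recursion, then counts from the Poisson observation model. A stationary
#' parameter set is the `M = 1` special case.
#'
#' @param params [plds_params()] or [switching_plds_params()].
#' @param T number of time bins.
#' @param seed optional integer seed.
#' @return list with `spikes` ([spike_data()]), `latents` (`d x T`),
#'   `regimes` (length-`T` integer, switching only), and `params`.
#' @export
simulate_trajectory <- function(params, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(T >= 1)
  switching <- inherits(params, "switching_plds_params")
  if (!switching) {
    sw <- switching_plds_params(list(params), matrix(1, 1, 1), 1)
  } else sw <- params
  d <- sw$d; C <- sw$C; M <- sw$M
  regimes <- integer(T)
  if (M == 1) {
    regimes[] <- 1L
  } else {
    regimes[1] <- sample.int(M, 1, prob = sw$pi)
    for (t in 2:T) {
      regimes[t] <- sample.int(M, 1, prob = sw$Phi[, regimes[t - 1]])
    }
  }
  # initial state from regime-1st-bin parameters
  p1 <- sw$regimes[[regimes[1]]]
  chol0 <- mat_sqrt(p1$Lambda0, warn = FALSE)
  x <- matrix(0, d, T)
  x0 <- p1$mu0 + as.vector(chol0 %*% stats::rnorm(d))
  sq <- lapply(sw$regimes, function(p) mat_sqrt(p$Q, warn = FALSE))
  prev <- x0
  for (t in seq_len(T)) {
    p <- sw$regimes[[regimes[t]]]
    prev <- as.vector(p$A %*% prev) + as.vector(sq[[regimes[t]]] %*% stats::rnorm(d))
    x[, t] <- prev
  }
  counts <- matrix(0L, C, T)
  for (t in seq_len(T)) {
    r <- plds_rate(x[, t], sw$regimes[[regimes[t]]])
    counts[, t] <- stats::rpois(C, r)
  }
  out <- list(params = params, latents = x,
              spikes = spike_data(counts, sw$delta))
  if (switching) out$regimes <- regimes
  out
}
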