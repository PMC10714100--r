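## Global Laplace inference: Newton maximization of the joint log posterior
## over the whole latent trajectory, with block-tridiagonal Hessian algebra.
## Posterior moments (diagonal and first off-diagonal covariance blocks) are
## extracted deterministically; a sampling mode is available for comparison.

# block-tridiagonal solve J z = rhs, J given by diagonal blocks D[[t]] and
# constant sub-diagonal block O (J[t+1, t] = O); returns z and the forward
# Schur complements S[[t]] for reuse
.block_tridiag_solve <- function(D, O, rhs) {
  Tn <- length(D)
  d <- nrow(O)
  S <- vector("list", Tn)
  y <- vector("list", Tn)
  S[[1]] <- D[[1]]
  y[[1]] <- rhs[[1]]
  for (t in 2:Tn) {
    SinvO <- psd_solve(S[[t - 1]], t(O))$x      # S^{-1} O'
    S[[t]] <- D[[t]] - O %*% SinvO
    y[[t]] <- rhs[[t]] - O %*% psd_solve(S[[t - 1]], cbind(y[[t - 1]]))$x[, 1]
  }
  z <- vector("list", Tn)
  z[[Tn]] <- psd_solve(S[[Tn]], cbind(y[[Tn]]))$x[, 1]
  for (t in (Tn - 1):1) {
    z[[t]] <- psd_solve(S[[t]], cbind(y[[t]] - t(O) %*% z[[t + 1]]))$x[, 1]
  }
  list(z = z, S = S)
}

#' Global Laplace approximation of the latent trajectory posterior
#'
#' Maximizes the joint log posterior `log f(x_{0:T} | n_{1:T})` by damped
#' Newton iteration (the objective is concave for the log-link Poisson
#' model), then reads posterior moments from the Gaussian approximation at
#' the mode. The Hessian is block-tridiagonal, so solves and the selected
#' inverse (diagonal and first off-diagonal blocks, which are all EM needs)
#' cost `O(T d^3)`.
#'
#' @param spikes [spike_data()].
#' @param params [plds_params()].
#' @param max_iter,tol Newton controls (tolerance on the mean step norm per
#'   time bin).
#' @param sample number of posterior samples; `0` (default) uses the
#'   deterministic moment extraction, otherwise moments are Monte-Carlo
#'   estimates from exact joint samples of the Laplace Gaussian.
#' @return a `smoother_trace`-compatible list: `xs`, `Ps`, `cross`
#'   (`cross[,,t] = E[x_t x_{t-1}']`, time 0 being the prior state), `x0`,
#'   `P0`.
#' @export
global_laplace <- function(spikes, params, max_iter = 50, tol = 1e-8,
                           sample = 0) {
  counts <- spikes$counts
  T <- ncol(counts); d <- params$d
  A <- params$A
  Qi <- psd_solve(params$Q, diag(d))$x
  L0i <- psd_solve(params$Lambda0, diag(d))$x
  AtQi <- t(A) %*% Qi
  AtQiA <- AtQi %*% A
  beta <- params$beta
  Tn <- T + 1                     # states x_0 .. x_T
  # initial guess: prior mean propagated
  X <- matrix(0, d, Tn)
  X[, 1] <- params$mu0
  for (t in 2:Tn) X[, t] <- A %*% X[, t - 1]

  obj <- function(X) {
    v <- -0.5 * sum((X[, 1] - params$mu0) * (L0i %*% (X[, 1] - params$mu0)))
    dx <- X[, 2:Tn, drop = FALSE] - A %*% X[, 1:T, drop = FALSE]
    v <- v - 0.5 * sum(dx * (Qi %*% dx))
    eta <- sweep(beta %*% X[, 2:Tn, drop = FALSE], 1, params$alpha, `+`)
    eta <- pmin(pmax(eta, -30), 30)
    v + sum(counts * eta - exp(eta))
  }
  f0 <- obj(X)
  for (it in seq_len(max_iter)) {
    eta <- sweep(beta %*% X[, 2:Tn, drop = FALSE], 1, params$alpha, `+`)
    eta <- pmin(pmax(eta, -30), 30)
    R <- exp(eta)                 # C x T expected counts at current point
    # gradient blocks
    g <- vector("list", Tn)
    dx <- X[, 2:Tn, drop = FALSE] - A %*% X[, 1:T, drop = FALSE]
    g[[1]] <- -as.vector(L0i %*% (X[, 1] - params$mu0)) + as.vector(AtQi %*% dx[, 1])
    for (t in 2:Tn) {
      gt <- -as.vector(Qi %*% dx[, t - 1]) +
        as.vector(crossprod(beta, counts[, t - 1] - R[, t - 1]))
      if (t < Tn) gt <- gt + as.vector(AtQi %*% dx[, t])
      g[[t]] <- gt
    }
    # negative-Hessian blocks (precision of the Laplace Gaussian)
    D <- vector("list", Tn)
    D[[1]] <- L0i + AtQiA
    for (t in 2:Tn) {
      H <- crossprod(beta, R[, t - 1] * beta)
      D[[t]] <- Qi + H + if (t < Tn) AtQiA else matrix(0, d, d)
    }
    O <- -Qi %*% A
    sol <- .block_tridiag_solve(D, O, g)
    step <- do.call(cbind, sol$z)
    a <- 1
    repeat {
      Xn <- X + a * step
      if (obj(Xn) >= f0 - 1e-10) break
      a <- a / 2
      if (a < 1e-6) { Xn <- X; break }
    }
    moved <- sqrt(mean((Xn - X)^2))
    X <- Xn; f0 <- obj(X)
    if (moved < tol) break
  }
  # final precision at the mode and its selected inverse
  eta <- sweep(beta %*% X[, 2:Tn, drop = FALSE], 1, params$alpha, `+`)
  eta <- pmin(pmax(eta, -30), 30)
  R <- exp(eta)
  D <- vector("list", Tn)
  D[[1]] <- L0i + AtQiA
  for (t in 2:Tn) {
    H <- crossprod(beta, R[, t - 1] * beta)
    D[[t]] <- Qi + H + if (t < Tn) AtQiA else matrix(0, d, d)
  }
  O <- -Qi %*% A
  S <- vector("list", Tn)
  S[[1]] <- D[[1]]
  for (t in 2:Tn) {
    S[[t]] <- D[[t]] - O %*% psd_solve(S[[t - 1]], t(O))$x
  }
  Sig <- vector("list", Tn)       # posterior covariance diagonal blocks
  Crs <- vector("list", Tn)       # Cov(x_t, x_{t-1}), index t+1
  Sig[[Tn]] <- symmetrize(psd_solve(S[[Tn]], diag(d))$x)
  for (t in (Tn - 1):1) {
    Sinv <- psd_solve(S[[t]], diag(d))$x
    SinvOt <- Sinv %*% t(O)
    Sig[[t]] <- symmetrize(Sinv + SinvOt %*% Sig[[t + 1]] %*% t(SinvOt))
    Crs[[t + 1]] <- -Sig[[t + 1]] %*% O %*% Sinv   # Cov(x_{t}, x_{t-1}) block
  }
  if (sample > 0) {
    # exact joint samples through the block Cholesky of the precision:
    # J = L L' with L lower block-bidiagonal; solve L' z = eps backwards
    G <- lapply(S, function(s) t(chol(symmetrize(s))))   # lower factors
    Z <- array(0, c(d, Tn, sample))
    for (s in seq_len(sample)) {
      z <- matrix(0, d, Tn)
      eps <- matrix(stats::rnorm(d * Tn), d, Tn)
      z[, Tn] <- backsolve(t(G[[Tn]]), eps[, Tn])
      for (t in (Tn - 1):1) {
        Mt <- O %*% t(solve(G[[t]]))                      # L_{t+1,t}' pieces
        z[, t] <- backsolve(t(G[[t]]), eps[, t] - t(Mt) %*% z[, t + 1])
      }
      Z[, , s] <- X + z
    }
    xs_all <- apply(Z, c(1, 2), mean)
    Sig <- lapply(seq_len(Tn), function(t) {
      zc <- sweep(Z[, t, , drop = TRUE], 1, xs_all[, t])
      symmetrize(tcrossprod(matrix(zc, d)) / sample)
    })
    Crs <- c(list(NULL), lapply(2:Tn, function(t) {
      zc1 <- sweep(matrix(Z[, t, , drop = TRUE], d), 1, xs_all[, t])
      zc0 <- sweep(matrix(Z[, t - 1, , drop = TRUE], d), 1, xs_all[, t - 1])
      tcrossprod(zc1, zc0) / sample
    }))
    X <- xs_all
  }
  xs <- X[, 2:Tn, drop = FALSE]
  Ps <- array(0, c(d, d, T))
  cross <- array(0, c(d, d, T))
  for (t in seq_len(T)) {
    Ps[, , t] <- Sig[[t + 1]]
    cross[, , t] <- Crs[[t + 1]] + tcrossprod(X[, t + 1], X[, t])
  }
  structure(list(xs = xs, Ps = Ps, cross = cross,
                 x0 = X[, 1], P0 = Sig[[1]]),
            class = "smoother_trace")
}
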