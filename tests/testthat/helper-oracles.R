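# Independent reference implementations used as oracles. These are written
# from textbook formulas and never call the package's filtering code paths.

# textbook Kalman filter for y_t = H x_t + b + v_t, v ~ N(0, R)
oracle_kalman_filter <- function(Y, A, Q, mu0, L0, H, b, R) {
  d <- nrow(A); T <- ncol(Y)
  xf <- matrix(0, d, T); xp <- xf
  Pf <- array(0, c(d, d, T)); Pp <- Pf
  m <- mu0; P <- L0
  loglik <- 0
  for (t in seq_len(T)) {
    mp <- as.vector(A %*% m); Ppred <- A %*% P %*% t(A) + Q
    S <- H %*% Ppred %*% t(H) + R
    innov <- Y[, t] - as.vector(H %*% mp) - b
    K <- Ppred %*% t(H) %*% solve(S)
    m <- mp + as.vector(K %*% innov)
    P <- Ppred - K %*% H %*% Ppred
    loglik <- loglik - 0.5 * (length(innov) * log(2 * pi) +
                                determinant(S)$modulus +
                                sum(innov * solve(S, innov)))
    xp[, t] <- mp; Pp[, , t] <- Ppred; xf[, t] <- m; Pf[, , t] <- (P + t(P)) / 2
  }
  list(xf = xf, Pf = Pf, xp = xp, Pp = Pp, loglik = as.numeric(loglik))
}

# textbook RTS smoother over the oracle filter output, including the time-0
# prior state and one-lag cross moments E[x_t x_{t-1}']
oracle_kalman_smoother <- function(kf, A, Q, mu0, L0) {
  d <- nrow(kf$xf); T <- ncol(kf$xf)
  xs <- kf$xf; Ps <- kf$Pf
  cross <- array(0, c(d, d, T))
  if (T > 1) {
    for (t in (T - 1):1) {
      G <- kf$Pf[, , t] %*% t(A) %*% solve(kf$Pp[, , t + 1])
      xs[, t] <- kf$xf[, t] + G %*% (xs[, t + 1] - kf$xp[, t + 1])
      Ps[, , t] <- kf$Pf[, , t] + G %*% (Ps[, , t + 1] - kf$Pp[, , t + 1]) %*% t(G)
      cross[, , t + 1] <- Ps[, , t + 1] %*% t(G) + tcrossprod(xs[, t + 1], xs[, t])
    }
  }
  G0 <- L0 %*% t(A) %*% solve(kf$Pp[, , 1])
  x0 <- as.vector(mu0 + G0 %*% (xs[, 1] - kf$xp[, 1]))
  P0 <- L0 + G0 %*% (Ps[, , 1] - kf$Pp[, , 1]) %*% t(G0)
  cross[, , 1] <- Ps[, , 1] %*% t(G0) + tcrossprod(xs[, 1], x0)
  list(xs = xs, Ps = Ps, cross = cross, x0 = x0, P0 = P0)
}

# one iteration of classical linear-Gaussian LDS-EM dynamics updates
oracle_lds_em_dynamics <- function(sm, T) {
  d <- nrow(sm$xs)
  Exx <- function(t) sm$Ps[, , t] + tcrossprod(sm$xs[, t])
  prev <- function(t) if (t == 1) sm$P0 + tcrossprod(sm$x0) else Exx(t - 1)
  S11 <- matrix(0, d, d); S10 <- S11; S00 <- S11
  for (t in seq_len(T)) {
    S11 <- S11 + Exx(t)
    S10 <- S10 + sm$cross[, , t]
    S00 <- S00 + prev(t)
  }
  A <- S10 %*% solve(S00)
  Q <- (S11 - A %*% t(S10) - S10 %*% t(A) + A %*% S00 %*% t(A)) / T
  list(A = A, Q = (Q + t(Q)) / 2, mu0 = sm$x0, Lambda0 = sm$P0)
}

# dense adaptive-quadrature posterior moments for a d = 1 Poisson update
oracle_quadrature_posterior <- function(m, P, n, alpha, beta) {
  dens <- function(x) {
    ll <- vapply(x, function(xi) {
      r <- exp(alpha + beta * xi)
      sum(dpois(n, r, log = TRUE))
    }, numeric(1))
    exp(ll) * dnorm(x, m, sqrt(P))
  }
  lo <- m - 10 * sqrt(P); hi <- m + 10 * sqrt(P)
  Z <- integrate(dens, lo, hi, rel.tol = 1e-10)$value
  mu <- integrate(function(x) x * dens(x), lo, hi, rel.tol = 1e-10)$value / Z
  v <- integrate(function(x) (x - mu)^2 * dens(x), lo, hi, rel.tol = 1e-10)$value / Z
  list(mean = mu, var = v)
}

# O(n^2) pairwise AUC with ties counted as half-wins
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# linear-Gaussian moment functions with the exact Gaussian predictive
# likelihood attached, for the generic switching filter path
lg_moments_with_loglik <- function(H, b, R) {
  m <- gaussian_moments(H, b, R)
  m$pred_loglik <- function(mean, cov, n) {
    S <- H %*% cov %*% t(H) + R
    innov <- n - as.vector(H %*% mean) - b
    as.numeric(-0.5 * (length(n) * log(2 * pi) + determinant(S)$modulus +
                         sum(innov * solve(S, innov))))
  }
  m
}

# exact smoothed regime probabilities for a linear-Gaussian switching system
# by enumerating all M^T regime sequences, each scored with a Kalman filter
oracle_switching_enumeration <- function(Y, As, Qs, mu0, L0, Hs, bs, Rs,
                                         Phi, pi0) {
  M <- length(As); T <- ncol(Y); d <- nrow(As[[1]])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), T)))
  logw <- numeric(nrow(seqs))
  for (k in seq_len(nrow(seqs))) {
    s <- seqs[k, ]
    lp <- log(pi0[s[1]])
    if (T > 1) for (t in 2:T) lp <- lp + log(Phi[s[t], s[t - 1]])
    # time-varying Kalman log-likelihood along this sequence
    m <- mu0; P <- L0; ll <- 0
    for (t in seq_len(T)) {
      j <- s[t]
      mp <- as.vector(As[[j]] %*% m)
      Pp <- As[[j]] %*% P %*% t(As[[j]]) + Qs[[j]]
      S <- Hs[[j]] %*% Pp %*% t(Hs[[j]]) + Rs[[j]]
      innov <- Y[, t] - as.vector(Hs[[j]] %*% mp) - bs[[j]]
      ll <- ll - 0.5 * (length(innov) * log(2 * pi) + determinant(S)$modulus +
                          sum(innov * solve(S, innov)))
      K <- Pp %*% t(Hs[[j]]) %*% solve(S)
      m <- mp + as.vector(K %*% innov)
      P <- Pp - K %*% Hs[[j]] %*% Pp
    }
    logw[k] <- lp + ll
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  probs <- matrix(0, M, T)
  for (t in seq_len(T)) {
    for (j in seq_len(M)) probs[j, t] <- sum(w[seqs[, t] == j])
  }
  probs
}

# small random PSD matrix
rand_psd <- function(d, scale = 1) {
  X <- matrix(rnorm(d * d), d)
  crossprod(X) / d * scale + diag(1e-3, d)
}

# shared harness for the M^T enumeration comparisons
enumeration_error <- function(seed, As, Qs, Hs, Rs, L0 = matrix(0.4)) {
  set.seed(seed)
  d <- 1; C <- 2; T <- 6; M <- 2
  bs <- list(c(0, 0), c(0, 0))
  mu0 <- 0
  Phi <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  pi0 <- c(0.6, 0.4)
  Y <- matrix(rnorm(C * T), C, T)
  spikes <- structure(list(counts = Y, delta = 1, C = C, T = T),
                      class = "spike_data")
  regimes <- lapply(1:M, function(j)
    plds_params(As[[j]], Qs[[j]], mu0, L0, rep(0, C), matrix(0, C, d), 1))
  params <- switching_plds_params(regimes, Phi, pi0)
  moments <- lapply(1:M, function(j) lg_moments_with_loglik(Hs[[j]], bs[[j]], Rs[[j]]))
  tr <- run_switching_filter(spikes, params, method = "pcf",
                             moments = moments, use_cpp = FALSE)
  sm <- run_switching_smoother(tr, params, use_cpp = FALSE)
  truth <- oracle_switching_enumeration(Y, As, Qs, mu0, L0, Hs, bs, Rs,
                                        Phi, pi0)
  max(abs(sm$Ws - truth))
}

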