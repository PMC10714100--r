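## Unsupervised learning: stationary EM (PCF-EM, PPF-EM, LEM) and switch EM
## (sPCF-EM, sPPF-EM). E-steps produce smoothed sufficient statistics; the
## M-steps are closed form for the dynamics and regime chain and a Newton
## solve of a concave per-neuron objective for the observation parameters.

#' E-step sufficient statistics for a stationary system
#'
#' Runs the requested inference method with the current parameters and
#' packages the smoothed moments EM needs.
#'
#' @param params current [plds_params()].
#' @param spikes [spike_data()].
#' @param method `"pcf"`, `"ppf"` (filter + RTS smoother) or
#'   `"global_laplace"` (whole-trajectory Newton).
#' @param rule [cubature_rule()].
#' @param loglik also record the per-step one-step predictive log-likelihood
#'   (pcf/ppf paths).
#' @return list of class `suff_stats` with smoothed means `Ex` (`d x T`),
#'   covariances `Vx` (`d x d x T`), one-lag cross moments `cross`
#'   (`cross[,,t] = E[x_t x_{t-1}']`, time 0 the prior state), prior-state
#'   moments `x0`, `P0`, and optionally `loglik`.
#' @export
estep_stationary <- function(params, spikes, method = c("pcf", "ppf", "global_laplace"),
                             rule = cubature_rule(params$d), loglik = FALSE) {
  method <- match.arg(method)
  if (method == "global_laplace") {
    sm <- global_laplace(spikes, params)
    ll <- NULL
  } else {
    tr <- run_filter(spikes, params, method = method, rule = rule,
                     loglik = loglik)
    sm <- rts_smooth(tr, params$A, params$Q, params$mu0, params$Lambda0)
    ll <- tr$loglik
  }
  if (any(!is.finite(sm$xs))) stop("non-finite smoothed statistics in E-step")
  structure(list(Ex = sm$xs, Vx = sm$Ps, cross = sm$cross,
                 x0 = sm$x0, P0 = sm$P0, T = ncol(sm$xs), d = params$d,
                 loglik = ll),
            class = "suff_stats")
}

# eigenvalue floor applied to learned covariances only when they have lost
# positive definiteness numerically; untouched otherwise so closed-form
# updates stay exact
.ensure_pd <- function(S, floor = 1e-10) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (ok) return(S)
  ee <- eigen(S, symmetric = TRUE)
  scale <- max(abs(ee$values), floor)
  symmetrize(ee$vectors %*% (pmax(ee$values, floor * scale) * t(ee$vectors)))
}

# second-moment sums for the dynamics update; prev-index sums include x_0
.dyn_sums <- function(Ex, Vx, cross, x0, P0, w = NULL) {
  T <- ncol(Ex); d <- nrow(Ex)
  if (is.null(w)) w <- rep(1, T)
  # flattened second moments E[x_t x_t'] as d^2 x T columns
  Exx <- matrix(Vx, d * d, T) +
    Ex[rep(seq_len(d), d), , drop = FALSE] *
    Ex[rep(seq_len(d), each = d), , drop = FALSE]
  S11 <- matrix(Exx %*% w, d, d)
  S10 <- matrix(matrix(cross, d * d, T) %*% w, d, d)
  S00 <- w[1] * (P0 + tcrossprod(x0))
  if (T > 1) {
    S00 <- S00 + matrix(Exx[, 1:(T - 1), drop = FALSE] %*% w[2:T], d, d)
  }
  list(S11 = S11, S10 = S10, S00 = S00, W = sum(w))
}

#' M-step for the dynamics parameters
#'
#' Closed-form maximizers of the expected complete-data log-likelihood:
#' `A = (sum E[x_t x_{t-1}']) (sum E[x_{t-1} x_{t-1}'])^{-1}` and the
#' matched residual covariance for `Q`; `mu0`, `Lambda0` from the smoothed
#' prior state. A ridge of `1e-8 * tr/d` is added if the Gram matrix is
#' singular.
#'
#' @param stats `suff_stats` from [estep_stationary()], or regime-weighted
#'   sums (internal switching use via `w`).
#' @param w optional per-time weights (switching regimes).
#' @return list with `A`, `Q`, `mu0`, `Lambda0`.
#' @export
mstep_dynamics <- function(stats, w = NULL) {
  s <- .dyn_sums(stats$Ex, stats$Vx, stats$cross, stats$x0, stats$P0, w)
  d <- nrow(s$S00)
  S00 <- s$S00
  A <- tryCatch(t(solve(S00, t(s$S10))),
                error = function(e) {
                  warning("singular Gram matrix in dynamics M-step; ridge added")
                  ridge <- 1e-8 * mean(diag(S00))
                  t(solve(S00 + diag(ridge, d), t(s$S10)))
                })
  Q <- symmetrize((s$S11 - A %*% t(s$S10) - s$S10 %*% t(A) +
                     A %*% S00 %*% t(A)) / s$W)
  list(A = A, Q = .ensure_pd(Q), mu0 = stats$x0,
       Lambda0 = .ensure_pd(symmetrize(stats$P0)))
}

# Newton maximization of the per-neuron observation objective
#   sum_t w_t [ n_t (a + b'm_t) - exp(a + b'm_t + b'S_t b / 2) ]
# Smat is d^2 x T (vectorized smoothed covariances); concave in (a, b).
.fit_obs_neuron <- function(n, m, Smat, w, a0, b0, max_iter = 100, tol = 1e-8) {
  d <- nrow(m)
  th <- c(a0, b0)
  Sb <- function(b) {      # S_t b for all t: d x T
    out <- matrix(0, d, ncol(m))
    for (l in seq_len(d)) {
      out <- out + Smat[((l - 1) * d + 1):(l * d), , drop = FALSE] * b[l]
    }
    out
  }
  value <- function(th) {
    u <- th[1] + as.vector(crossprod(m, th[-1]))
    v <- 0.5 * as.vector(crossprod(Sb(th[-1]), th[-1]))
    sum(w * (n * u - exp(pmin(u + v, 30))))
  }
  f0 <- value(th)
  for (it in seq_len(max_iter)) {
    a <- th[1]; b <- th[-1]
    Sbt <- Sb(b)                               # d x T
    u <- a + as.vector(crossprod(m, b))
    v <- 0.5 * colSums(Sbt * b)
    gexp <- exp(pmin(u + v, 30))
    wg <- w * gexp
    mm <- m + Sbt                              # d x T: m_t + S_t b
    grad <- c(sum(w * n) - sum(wg),
              as.vector(m %*% (w * n)) - as.vector(mm %*% wg))
    Haa <- sum(wg)
    Hab <- as.vector(mm %*% wg)
    SW <- matrix(Smat %*% wg, d, d)            # weighted sum of S_t
    Hbb <- mm %*% (wg * t(mm)) + SW
    H <- rbind(c(Haa, Hab), cbind(Hab, Hbb))   # negative Hessian (PD)
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-10 * mean(diag(H)), d + 1), grad))
    al <- 1
    repeat {
      thn <- th + al * step
      fn <- value(thn)
      if (fn >= f0 - 1e-12) break
      al <- al / 2
      if (al < 1e-8) { thn <- th; fn <- f0; break }
    }
    moved <- sqrt(sum((thn - th)^2))
    th <- thn; f0 <- fn
    if (moved < tol) break
  }
  list(alpha = th[1], beta = th[-1], converged = it < max_iter || moved < tol)
}

#' M-step for the observation parameters
#'
#' Maximizes, per neuron, the expected complete-data Poisson likelihood
#' `sum_t w_t [ n_t (alpha + beta' m_t) - E exp(alpha + beta' x_t) ]` where
#' the Gaussian expectation has the exact log-normal closed form
#' `exp(alpha + beta' m_t + beta' S_t beta / 2)`. The objective is concave;
#' a damped Newton iteration with warm starts is used. Columns may be
#' concatenated across regimes with regime-probability weights, which gives
#' both the regime-specific and the shared-observation switching updates.
#'
#' @param counts `C x T'` counts aligned with the moment columns.
#' @param m `d x T'` smoothed means.
#' @param V `d x d x T'` smoothed covariances.
#' @param w length-`T'` weights.
#' @param alpha0,beta0 warm starts.
#' @param use_cpp use the compiled Newton solver (the R path is the
#'   reference implementation).
#' @return list with `alpha` (length `C`), `beta` (`C x d`), `n_failed`.
#' @export
mstep_observation <- function(counts, m, V, w = NULL, alpha0, beta0,
                              use_cpp = TRUE) {
  C <- nrow(counts); d <- nrow(m); T <- ncol(m)
  if (is.null(w)) w <- rep(1, T)
  Smat <- matrix(V, d * d, T)
  if (use_cpp) {
    out <- mstep_observation_cpp(counts, m, Smat, w, alpha0,
                                 as.matrix(beta0), 100L, 1e-8)
    out$alpha <- as.vector(out$alpha)
    if (out$n_failed > 0) {
      warning(out$n_failed, " neuron(s) kept previous observation parameters")
    }
    return(out)
  }
  alpha <- alpha0; beta <- beta0
  failed <- 0L
  for (i in seq_len(C)) {
    fit <- .fit_obs_neuron(counts[i, ], m, Smat, w, alpha0[i], beta0[i, ])
    if (fit$converged) {
      alpha[i] <- fit$alpha; beta[i, ] <- fit$beta
    } else {
      failed <- failed + 1L
    }
  }
  if (failed > 0) warning(failed, " neuron(s) kept previous observation parameters")
  list(alpha = alpha, beta = beta, n_failed = failed)
}

#' M-step for the regime chain
#'
#' `Phi[j, i] = sum_t P(s_t=j, s_{t-1}=i | n) / sum_t P(s_{t-1}=i | n)` with
#' columns renormalized; `pi = P(s_1 | n)`. A regime never visited yields a
#' uniform column with a warning.
#'
#' @param Ws `M x T` smoothed regime probabilities.
#' @param pairwise `M x M x T` pairwise probabilities (slice 1 unused).
#' @return list with `Phi`, `pi`.
#' @export
mstep_regime_chain <- function(Ws, pairwise) {
  M <- nrow(Ws); T <- ncol(Ws)
  num <- matrix(0, M, M)
  if (T > 1) for (t in 2:T) num <- num + pairwise[, , t]
  Phi <- num
  for (i in seq_len(M)) {
    tot <- sum(num[, i])
    if (tot <= 0) {
      warning("regime ", i, " never visited; uniform transition column")
      Phi[, i] <- 1 / M
    } else {
      Phi[, i] <- num[, i] / tot
    }
  }
  list(Phi = Phi, pi = Ws[, 1] / sum(Ws[, 1]))
}

#' Expected complete-data log-likelihood of a stationary model
#'
#' Evaluates the EM surrogate objective at `params` given fixed smoothed
#' statistics, using the log-normal closed form for the Poisson expectation
#' term. Used to verify that M-steps never decrease the objective.
#'
#' @param params [plds_params()].
#' @param stats `suff_stats`.
#' @param spikes [spike_data()].
#' @return scalar objective value.
#' @export
expected_complete_loglik <- function(params, stats, spikes) {
  d <- params$d; T <- stats$T
  s <- .dyn_sums(stats$Ex, stats$Vx, stats$cross, stats$x0, stats$P0)
  Qi <- psd_solve(params$Q, diag(d))$x
  A <- params$A
  resid <- s$S11 - A %*% t(s$S10) - s$S10 %*% t(A) + A %*% s$S00 %*% t(A)
  v_dyn <- -0.5 * (T * (d * log(2 * pi) + determinant(params$Q)$modulus) +
                     sum(Qi * resid))
  L0i <- psd_solve(params$Lambda0, diag(d))$x
  dm <- stats$x0 - params$mu0
  v0 <- -0.5 * (d * log(2 * pi) + determinant(params$Lambda0)$modulus +
                  sum(L0i * (stats$P0 + tcrossprod(dm))))
  Smat <- matrix(stats$Vx, d * d, T)
  v_obs <- 0
  for (i in seq_len(params$C)) {
    b <- params$beta[i, ]
    u <- params$alpha[i] + as.vector(crossprod(stats$Ex, b))
    Sb <- matrix(0, d, T)
    for (l in seq_len(d)) {
      Sb <- Sb + Smat[((l - 1) * d + 1):(l * d), , drop = FALSE] * b[l]
    }
    v <- 0.5 * colSums(Sb * b)
    v_obs <- v_obs + sum(spikes$counts[i, ] * u - exp(pmin(u + v, 30)) -
                           lgamma(spikes$counts[i, ] + 1))
  }
  as.numeric(v_dyn + v0 + v_obs)
}

# random initialization; the dynamics start at 0.9 I and the rest from
# documented simple distributions
.init_stationary <- function(spikes, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(spikes$counts); T <- ncol(spikes$counts)
  mean_counts <- pmax(rowMeans(spikes$counts), 1 / T)
  plds_params(A = diag(0.9, d), Q = diag(0.02, d), mu0 = rep(0, d),
              Lambda0 = diag(1, d), alpha = log(mean_counts),
              beta = matrix(stats::rnorm(C * d, sd = 0.1), C, d),
              delta = spikes$delta)
}

#' Fit a stationary Poisson LDS by EM
#'
#' Alternates the chosen E-step with the closed-form dynamics update and the
#' Newton observation update. A fixed iteration budget is used (with an
#' optional early stop on the relative change of the diagnostic over 10
#' iterations); the per-iteration one-step predictive log-likelihood on the
#' training data is recorded.
#'
#' @param spikes [spike_data()].
#' @param d latent dimension.
#' @param method `"pcf"`, `"ppf"` or `"global_laplace"`.
#' @param iterations EM iteration budget.
#' @param init optional [plds_params()] initialization; by default `A` is
#'   `0.9 I` and the remaining parameters are drawn from simple documented
#'   distributions.
#' @param seed seed for the random initialization.
#' @param rule [cubature_rule()].
#' @param early_stop_tol optional relative-change tolerance (e.g. `1e-6`);
#'   `NULL` disables early stopping.
#' @return an `em_result`: `params`, `diagnostics` (data frame with
#'   `iteration`, `pred_loglik`), `iterations_run`, `init_id`, `seed`.
#' @export
fit_plds_em <- function(spikes, d, method = c("pcf", "ppf", "global_laplace"),
                        iterations = 300, init = NULL, seed = NULL,
                        rule = cubature_rule(d), early_stop_tol = NULL) {
  method <- match.arg(method)
  params <- init %||% .init_stationary(spikes, d, seed)
  diag_ll <- numeric(0)
  base <- if (method == "global_laplace") "ppf" else method
  it <- 0
  while (it < iterations) {
    it <- it + 1
    st <- estep_stationary(params, spikes, method = method, rule = rule,
                           loglik = (method != "global_laplace"))
    ll <- st$loglik
    if (is.null(ll)) {
      tr <- run_filter(spikes, params, method = base, rule = rule, loglik = TRUE)
      ll <- tr$loglik
    }
    diag_ll <- c(diag_ll, sum(ll))
    dyn <- mstep_dynamics(st)
    obs <- mstep_observation(spikes$counts, st$Ex, st$Vx,
                             alpha0 = params$alpha, beta0 = params$beta)
    params <- plds_params(A = dyn$A, Q = dyn$Q, mu0 = dyn$mu0,
                          Lambda0 = dyn$Lambda0, alpha = obs$alpha,
                          beta = obs$beta, delta = spikes$delta)
    if (!all(is.finite(diag_ll))) stop("non-finite EM diagnostic; aborting")
    if (!is.null(early_stop_tol) && it >= 10) {
      recent <- diag_ll[(it - 9):it]
      rel <- abs(recent[10] - recent[1]) / (abs(recent[1]) + 1e-12)
      if (rel < early_stop_tol) break
    }
  }
  structure(list(params = params,
                 diagnostics = data.frame(iteration = seq_along(diag_ll),
                                          pred_loglik = diag_ll),
                 iterations_run = it, method = method, init_id = 1L,
                 seed = seed),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM fit (%s): %d iterations", x$method, x$iterations_run))
  if (nrow(x$diagnostics) > 0) {
    cat(sprintf(", final one-step predictive loglik %.2f",
                utils::tail(x$diagnostics$pred_loglik, 1)))
  }
  cat("\n")
  invisible(x)
}

.init_switching <- function(spikes, d, M, seed = NULL, dwell_init = 4,
                            shared_observation = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(spikes$counts); T <- ncol(spikes$counts)
  mean_counts <- pmax(rowMeans(spikes$counts), 1 / T)
  shared_beta <- matrix(stats::rnorm(C * d, sd = 0.1), C, d)
  regimes <- lapply(seq_len(M), function(j) {
    beta <- if (shared_observation) shared_beta else
      matrix(stats::rnorm(C * d, sd = 0.1), C, d)
    plds_params(A = diag(0.9, d), Q = diag(0.02, d), mu0 = rep(0, d),
                Lambda0 = diag(1, d), alpha = log(mean_counts), beta = beta,
                delta = spikes$delta)
  })
  p_stay <- 1 - spikes$delta / dwell_init
  Phi <- matrix((1 - p_stay) / max(M - 1, 1), M, M)
  diag(Phi) <- if (M == 1) 1 else p_stay
  switching_plds_params(regimes, Phi, rep(1 / M, M))
}

.params_finite <- function(p) {
  if (inherits(p, "switching_plds_params")) {
    return(all(vapply(p$regimes, .params_finite, logical(1))) &&
             all(is.finite(p$Phi)) && all(is.finite(p$pi)))
  }
  all(is.finite(p$A)) && all(is.finite(p$Q)) && all(is.finite(p$alpha)) &&
    all(is.finite(p$beta)) && all(is.finite(p$mu0)) && all(is.finite(p$Lambda0))
}

# one switch-EM iteration: switching filter + smoother E-step, then the
# regime-weighted M-steps
.switch_em_iter <- function(params, spikes, base, rule, shared_observation) {
  M <- params$M; d <- params$d; T <- ncol(spikes$counts)
  tr <- run_switching_filter(spikes, params, method = base, rule = rule)
  sm <- run_switching_smoother(tr, params)
  Ws <- sm$Ws
  if (any(!is.finite(Ws))) stop("non-finite smoothed regime weights")
  collapse <- which(rowSums(Ws) < 1e-6 * T)
  if (length(collapse) > 0) {
    message("regime(s) ", paste(collapse, collapse = ", "),
            " have near-zero total weight this iteration")
  }
  chain <- mstep_regime_chain(Ws, sm$pairwise)
  # prior-state moments: mixture over s_1 of the regime-conditioned x0 stats
  mix0 <- .mix_gaussians(
    do.call(cbind, lapply(seq_len(M), function(j) sm$x_prev[[j]][, 1])),
    lapply(seq_len(M), function(j) sm$P_prev[[j]][, , 1]),
    Ws[, 1])
  old <- params$regimes
  new_regimes <- vector("list", M)
  for (j in seq_len(M)) {
    if (sum(Ws[j, ]) < 1e-6 * T) {
      # collapsed regime: keep its previous dynamics, learning continues
      new_regimes[[j]] <- list(A = old[[j]]$A, Q = old[[j]]$Q)
      next
    }
    # weighted dynamics update; the t = 1 "previous" moments are the
    # regime-conditioned prior-state stats
    wj <- Ws[j, ]
    s <- .dyn_sums(sm$xs[[j]], sm$Ps[[j]], sm$cross[[j]],
                   sm$x_prev[[j]][, 1], sm$P_prev[[j]][, , 1], wj)
    A <- tryCatch(t(psd_solve(s$S00, t(s$S10))$x),
                  error = function(e) old[[j]]$A)
    Q <- symmetrize((s$S11 - A %*% t(s$S10) - s$S10 %*% t(A) +
                       A %*% s$S00 %*% t(A)) / max(s$W, 1e-12))
    # a sparsely weighted regime can produce a near-exact unstable fit
    # (huge spectral radius, vanishing Q) that blows up the next E-step;
    # such updates are rejected and the previous dynamics kept
    rho <- if (all(is.finite(A))) {
      max(Mod(eigen(A, only.values = TRUE)$values))
    } else Inf
    if (rho > 1.05) {
      message("regime ", j, ": unstable dynamics update rejected (spectral radius ",
              round(rho, 2), ")")
      new_regimes[[j]] <- list(A = old[[j]]$A, Q = old[[j]]$Q)
    } else {
      # small absolute noise floor keeps the filter from turning
      # overconfident when a regime momentarily explains few bins
      ee <- eigen(symmetrize(Q), symmetric = TRUE)
      Qf <- symmetrize(ee$vectors %*% (pmax(ee$values, 1e-4) * t(ee$vectors)))
      new_regimes[[j]] <- list(A = A, Q = Qf)
    }
  }
  if (shared_observation) {
    mcat <- do.call(cbind, sm$xs)
    Vcat <- array(unlist(sm$Ps), c(d, d, M * T))
    wcat <- as.vector(t(Ws))
    ncat <- do.call(cbind, rep(list(spikes$counts), M))
    obs <- mstep_observation(ncat, mcat, Vcat, wcat,
                             alpha0 = old[[1]]$alpha, beta0 = old[[1]]$beta)
    obs_list <- rep(list(obs), M)
  } else {
    obs_list <- lapply(seq_len(M), function(j)
      mstep_observation(spikes$counts, sm$xs[[j]], sm$Ps[[j]], Ws[j, ],
                        alpha0 = old[[j]]$alpha, beta0 = old[[j]]$beta))
  }
  L0 <- .ensure_pd(mix0$cov)
  regimes <- lapply(seq_len(M), function(j) {
    plds_params(A = new_regimes[[j]]$A, Q = new_regimes[[j]]$Q,
                mu0 = mix0$mean, Lambda0 = L0,
                alpha = obs_list[[j]]$alpha, beta = obs_list[[j]]$beta,
                delta = spikes$delta)
  })
  list(params = switching_plds_params(regimes, chain$Phi, chain$pi),
       loglik = sum(tr$loglik))
}

#' Fit a switching Poisson LDS by switch EM
#'
#' The E-step runs the switching filter (bank of per-regime PCF or PPF
#' filters with IMM mixing) followed by the switching smoother; the M-step
#' applies the regime-weighted closed-form dynamics update, the Newton
#' observation update (optionally shared across regimes) and the closed-form
#' regime-chain update. Multiple seeded initializations can be run, the
#' returned fit being the one with the best training-set neural
#' self-prediction (predictive power).
#'
#' @param spikes [spike_data()].
#' @param d latent dimension.
#' @param M number of regimes.
#' @param method `"spcf"` (PCF embedded) or `"sppf"` (PPF embedded).
#' @param iterations EM iteration budget per initialization.
#' @param n_inits number of random initializations.
#' @param seed master seed; initialization `k` uses `seed + k - 1`.
#' @param shared_observation share observation parameters across regimes.
#' @param dwell_init initial dwell time (seconds) encoded in `Phi`.
#' @param rule [cubature_rule()].
#' @param init optional explicit [switching_plds_params()] initialization
#'   (used for all inits; only sensible with `n_inits = 1`).
#' @return an `em_result` with fields as in [fit_plds_em()] plus `train_pp`
#'   (selected initialization's training predictive power) and `all_inits`
#'   (per-initialization summary data frame).
#' @export
fit_switching_em <- function(spikes, d, M, method = c("spcf", "sppf"),
                             iterations = 300, n_inits = 1, seed = NULL,
                             shared_observation = FALSE, dwell_init = 4,
                             rule = cubature_rule(d), init = NULL) {
  method <- match.arg(method)
  base <- if (method == "spcf") "pcf" else "ppf"
  results <- vector("list", n_inits)
  for (k in seq_len(n_inits)) {
    kseed <- if (is.null(seed)) NULL else seed + k - 1
    params <- init %||% .init_switching(spikes, d, M, kseed, dwell_init,
                                        shared_observation)
    diag_ll <- numeric(0)
    it <- 0
    ok <- TRUE
    while (it < iterations) {
      it <- it + 1
      step <- tryCatch(.switch_em_iter(params, spikes, base, rule,
                                       shared_observation),
                       error = function(e) e)
      if (inherits(step, "error")) {
        warning("switch EM aborted at iteration ", it, ": ",
                conditionMessage(step))
        ok <- FALSE
        break
      }
      if (!.params_finite(step$params)) {
        warning("switch EM produced non-finite parameters at iteration ", it,
                "; keeping the previous iterate")
        ok <- FALSE
        break
      }
      params <- step$params
      diag_ll <- c(diag_ll, step$loglik)
    }
    # training predictive power for initialization selection
    pp <- tryCatch({
      tr <- run_switching_filter(spikes, params, method = base, rule = rule,
                                 spike_probs = TRUE)
      predictive_power(tr$spike_prob, spikes)
    }, error = function(e) -Inf)
    results[[k]] <- structure(
      list(params = params,
           diagnostics = data.frame(iteration = seq_along(diag_ll),
                                    pred_loglik = diag_ll),
           iterations_run = length(diag_ll), method = method,
           init_id = k, seed = kseed, train_pp = pp, converged_ok = ok),
      class = "em_result")
  }
  pps <- vapply(results, function(r) r$train_pp, numeric(1))
  best <- which.max(pps)
  out <- results[[best]]
  out$all_inits <- data.frame(init_id = seq_len(n_inits), train_pp = pps)
  out$init_params <- lapply(results, function(r) r$params)
  out
}
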