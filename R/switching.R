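## Switching-system inference: a bank of per-regime stationary filters with
## IMM-style destination-conditioned mixing, the regime posterior from
## cubature predictive likelihoods, and a switching smoother producing every
## expectation the switch EM needs.

#' Log predictive likelihood of one bin under a regime's prediction
#'
#' `log E_x[P(n_t | x)]` with `x` drawn from the predicted Gaussian of one
#' regime; the cubature sum is evaluated with a max-shift for stability.
#' Used as the per-regime emission score in the switching filter.
#'
#' @param pred predicted [gaussian_belief()] for the regime.
#' @param n counts for one bin.
#' @param params the regime's [plds_params()].
#' @param rule [cubature_rule()].
#' @return scalar log predictive likelihood.
#' @export
switching_predictive_loglik <- function(pred, n, params,
                                        rule = cubature_rule(length(pred$mean))) {
  predictive_log_likelihood(pred, n, params, rule)
}

# moment-matched mixture of Gaussians: means d x M, covs list, weights
.mix_gaussians <- function(means, covs, wts) {
  mu <- as.vector(means %*% wts)
  d <- length(mu)
  S <- matrix(0, d, d)
  for (i in seq_along(wts)) {
    dm <- means[, i] - mu
    S <- S + wts[i] * (covs[[i]] + tcrossprod(dm))
  }
  list(mean = mu, cov = symmetrize(S))
}

#' Run the switching filter
#'
#' Each step performs (i) destination-conditioned mixing: for every regime
#' `j`, the previous per-regime posteriors are combined with weights
#' proportional to `Phi[j, i] * P(s_{t-1} = i | n_{1:t-1})` and moment-matched
#' into `f(x_{t-1} | n_{1:t-1}, s_t = j)`; (ii) a per-regime prediction and
#' PCF/PPF update; (iii) the regime posterior
#' `P(s_t = j | n_{1:t}) proportional to L_j * sum_i Phi[j,i] P(s_{t-1}=i | .)`
#' with `L_j` the regime's predictive likelihood, computed in the log domain
#' and renormalized.
#'
#' @param spikes [spike_data()].
#' @param params [switching_plds_params()].
#' @param method base filter, `"pcf"` or `"ppf"`.
#' @param rule [cubature_rule()].
#' @param moments optional list of `M` moment-function lists; forces the
#'   generic R path (each must carry `pred_loglik(mean, cov, n)`).
#' @param spike_probs also compute mixture one-step-ahead spike
#'   probabilities (regime weights are the one-step-ahead regime predictions
#'   `Phi %*% P(s_{t-1} | n_{1:t-1})`).
#' @param use_cpp use the compiled Poisson fast path.
#' @param one_step classical one-step PPF variant.
#' @return a `switch_filter_trace` with filtered regime probabilities
#'   `w_filt` (`M x T`), predicted regime probabilities `w_pred`, per-regime
#'   log predictive likelihoods `ell`, per-step data log-likelihood `loglik`,
#'   per-regime beliefs (`xf`, `Pf`, `xp`, `Pp`, `xmix`, `Pmix` as lists over
#'   regimes), the moment-matched `merged_mean`, and optional `spike_prob`.
#' @export
run_switching_filter <- function(spikes, params, method = c("pcf", "ppf"),
                                 rule = cubature_rule(params$d),
                                 moments = NULL, spike_probs = FALSE,
                                 use_cpp = TRUE, one_step = FALSE) {
  method <- match.arg(method)
  M <- params$M; d <- params$d; C <- params$C
  counts <- spikes$counts
  T <- ncol(counts)
  if (is.null(moments) && use_cpp) {
    Ac <- array(0, c(d, d, M)); Qc <- Ac; L0 <- Ac
    mu0 <- matrix(0, d, M); al <- matrix(0, C, M)
    be <- array(0, c(C, d, M))
    for (j in seq_len(M)) {
      p <- params$regimes[[j]]
      Ac[, , j] <- p$A; Qc[, , j] <- p$Q; L0[, , j] <- p$Lambda0
      mu0[, j] <- p$mu0; al[, j] <- p$alpha; be[, , j] <- p$beta
    }
    out <- switching_filter_cpp(counts, Ac, Qc, mu0, L0, al, be,
                                params$Phi, params$pi, rule$points,
                                rule$weights, method == "ppf", one_step,
                                spike_probs)
    out$loglik <- as.vector(out$loglik)
    out$method <- method
    out$params <- params
    return(structure(out, class = "switch_filter_trace"))
  }
  if (is.null(moments)) {
    moments <- lapply(params$regimes, function(p) {
      m <- poisson_moments(p)
      m$pred_loglik <- function(mean, cov, n)
        predictive_log_likelihood(gaussian_belief(mean, cov, "predicted"),
                                  n, p, rule)
      m
    })
  }
  w_filt <- matrix(0, M, T); w_pred <- matrix(0, M, T); ell <- matrix(0, M, T)
  loglik <- numeric(T)
  xf <- lapply(seq_len(M), function(j) matrix(0, d, T))
  xp <- xf; xmix <- xf
  Pf <- lapply(seq_len(M), function(j) array(0, c(d, d, T)))
  Pp <- Pf; Pmix <- Pf
  sp <- if (spike_probs) matrix(0, C, T) else NULL
  merged <- matrix(0, d, T)
  mprev <- lapply(params$regimes, function(p) p$mu0)
  Pprev <- lapply(params$regimes, function(p) p$Lambda0)
  wprev <- params$pi
  for (t in seq_len(T)) {
    n <- counts[, t]
    pr <- numeric(M)
    spj <- if (spike_probs) matrix(0, C, M) else NULL
    for (j in seq_len(M)) {
      pj <- params$regimes[[j]]
      if (t == 1) {
        mmix <- pj$mu0; Pmx <- pj$Lambda0; pr[j] <- params$pi[j]
      } else {
        num <- params$Phi[j, ] * wprev
        pr[j] <- sum(num)
        mu_ij <- if (pr[j] > 0) num / pr[j] else rep(1 / M, M)
        mix <- .mix_gaussians(do.call(cbind, mprev), Pprev, mu_ij)
        mmix <- mix$mean; Pmx <- mix$cov
      }
      xmix[[j]][, t] <- mmix; Pmix[[j]][, , t] <- Pmx
      pred <- predict_belief(gaussian_belief(mmix, Pmx, "filtered"), pj$A, pj$Q)
      xp[[j]][, t] <- pred$mean; Pp[[j]][, , t] <- pred$cov
      bel <- if (method == "pcf") {
        pcf_update(pred, n, moments[[j]], rule)$belief
      } else {
        ppf_update(pred, n, pj, one_step = one_step)
      }
      xf[[j]][, t] <- bel$mean; Pf[[j]][, , t] <- bel$cov
      ell[j, t] <- moments[[j]]$pred_loglik(pred$mean, pred$cov, n)
      if (spike_probs) spj[, j] <- one_step_spike_prob(pred, pj, rule)
    }
    w_pred[, t] <- pr
    lognum <- ifelse(pr > 0, log(pr), -Inf) + ell[, t]
    mx <- max(lognum)
    if (!is.finite(mx)) {
      warning("all regime weights vanished; uniform fallback")
      wnew <- rep(1 / M, M)
      loglik[t] <- -Inf
    } else {
      wnew <- exp(lognum - mx)
      loglik[t] <- mx + log(sum(wnew))
      wnew <- wnew / sum(wnew)
    }
    w_filt[, t] <- wnew
    if (spike_probs) sp[, t] <- spj %*% pr
    merged[, t] <- do.call(cbind, lapply(seq_len(M), function(j) xf[[j]][, t])) %*% wnew
    mprev <- lapply(seq_len(M), function(j) xf[[j]][, t])
    Pprev <- lapply(seq_len(M), function(j) Pf[[j]][, , t, drop = FALSE][, , 1])
    wprev <- wnew
  }
  structure(list(w_filt = w_filt, w_pred = w_pred, ell = ell, loglik = loglik,
                 xf = xf, Pf = Pf, xp = xp, Pp = Pp, xmix = xmix, Pmix = Pmix,
                 merged_mean = merged, spike_prob = sp, method = method,
                 params = params),
            class = "switch_filter_trace")
}

#' Run the switching smoother
#'
#' Backward pass with three pieces. (i) Smoothed regime probabilities
#' `P(s_t | n_{1:T})` and pairwise probabilities
#' `P(s_{t+1} = j, s_t = i | n_{1:T})` by expectation correction: for every
#' regime pair the filtered belief of regime `i` is predicted through regime
#' `j`'s dynamics, and the backward conditional
#' `P(s_t = i | s_{t+1} = j, n_{1:T})` is proportional to the filtered
#' weight times a Gaussian overlap factor: the pair prediction density
#' evaluated at the smoothed mean of `(t+1, j)` (the bin-likelihood factor
#' is constant in the source regime and cancels in the normalization). The
#' overlap factor re-injects the information future observations carry
#' about the regime through the continuous state. Marginal consistency
#' holds by construction. (ii) Per-regime smoothed latents
#' `f(x_t | n_{1:T}, s_t = i)` by pair-conditioned RTS steps moment-matched
#' over the successor regime. (iii) The regime-conditioned one-lag moments
#' `E[x_{t-1} | .]`, `Cov[x_{t-1} | .]` and `E[x_t x_{t-1}' | ., s_t = j]`
#' anchored at the filter's mixed priors — exactly the statistics the switch
#' EM M-step needs.
#'
#' @param trace a `switch_filter_trace` from [run_switching_filter()].
#' @param params the [switching_plds_params()] used to produce it.
#' @param use_cpp use the compiled backward pass.
#' @return a `switch_smoother_trace` with `Ws` (`M x T` smoothed regime
#'   probs), `pairwise` (`M x M x T`, slice t = `P(s_t=j, s_{t-1}=i)`, slice
#'   1 unused), per-regime `xs`, `Ps`, `x_prev`, `P_prev`, `cross`, and the
#'   moment-matched `merged_mean` / `merged_cov`.
#' @export
run_switching_smoother <- function(trace, params, use_cpp = TRUE) {
  M <- params$M; d <- params$d
  T <- ncol(trace$w_filt)
  if (use_cpp) {
    Ac <- array(0, c(d, d, M)); Qc <- Ac
    for (j in seq_len(M)) {
      Ac[, , j] <- params$regimes[[j]]$A
      Qc[, , j] <- params$regimes[[j]]$Q
    }
    out <- switching_smoother_cpp(trace, Ac, Qc, params$Phi)
    return(structure(out, class = "switch_smoother_trace"))
  }
  w_filt <- trace$w_filt
  Ws <- matrix(0, M, T)
  pairwise <- array(0, c(M, M, T))
  Ws[, T] <- w_filt[, T]
  xs <- lapply(seq_len(M), function(j) trace$xf[[j]])
  Ps <- lapply(seq_len(M), function(j) trace$Pf[[j]])
  log_mvn <- function(x, mu, S) {
    R <- chol(symmetrize(S) + diag(1e-12, nrow(S)))
    z <- backsolve(R, x - mu, transpose = TRUE)
    -0.5 * (length(x) * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
  }
  if (T > 1) {
    for (t in (T - 1):1) {
      log_rho <- matrix(-Inf, M, M)          # [i at t, j at t+1]
      cm <- array(0, c(d, M, M)); cP <- array(0, c(d, d, M, M))
      for (j in seq_len(M)) {
        Aj <- params$regimes[[j]]$A; Qj <- params$regimes[[j]]$Q
        for (i in seq_len(M)) {
          Pfi <- trace$Pf[[i]][, , t]
          a <- as.vector(Aj %*% trace$xf[[i]][, t])
          A <- symmetrize(Aj %*% Pfi %*% t(Aj) + Qj)
          z <- log_mvn(xs[[j]][, t + 1], a, A)
          lphi <- if (params$Phi[j, i] > 0) log(params$Phi[j, i]) else -Inf
          lw <- if (w_filt[i, t] > 0) log(w_filt[i, t]) else -Inf
          log_rho[i, j] <- lw + lphi + z
          G <- t(psd_solve(A, Aj %*% Pfi)$x)
          cm[, i, j] <- trace$xf[[i]][, t] +
            as.vector(G %*% (xs[[j]][, t + 1] - a))
          cP[, , i, j] <- symmetrize(Pfi + G %*% (Ps[[j]][, , t + 1] - A) %*% t(G))
        }
      }
      for (j in seq_len(M)) {
        lr <- log_rho[, j]
        mx <- max(lr)
        cond <- if (is.finite(mx)) {
          e <- exp(lr - mx); e / sum(e)
        } else rep(1 / M, M)
        pairwise[j, , t + 1] <- Ws[j, t + 1] * cond
      }
      Ws[, t] <- colSums(pairwise[, , t + 1])
      for (i in seq_len(M)) {
        wk <- pairwise[, i, t + 1]
        wk <- if (sum(wk) > 0) wk / sum(wk) else rep(1 / M, M)
        mix <- .mix_gaussians(matrix(cm[, i, ], d, M),
                              lapply(seq_len(M), function(j) cP[, , i, j]), wk)
        xs[[i]][, t] <- mix$mean
        Ps[[i]][, , t] <- mix$cov
      }
    }
  }
  x_prev <- lapply(seq_len(M), function(j) matrix(0, d, T))
  P_prev <- lapply(seq_len(M), function(j) array(0, c(d, d, T)))
  cross <- P_prev
  for (t in seq_len(T)) {
    for (j in seq_len(M)) {
      Aj <- params$regimes[[j]]$A
      G <- t(psd_solve(trace$Pp[[j]][, , t], Aj %*% trace$Pmix[[j]][, , t])$x)
      xprev <- trace$xmix[[j]][, t] +
        as.vector(G %*% (xs[[j]][, t] - trace$xp[[j]][, t]))
      x_prev[[j]][, t] <- xprev
      P_prev[[j]][, , t] <- symmetrize(trace$Pmix[[j]][, , t] +
        G %*% (Ps[[j]][, , t] - trace$Pp[[j]][, , t]) %*% t(G))
      cross[[j]][, , t] <- Ps[[j]][, , t] %*% t(G) + tcrossprod(xs[[j]][, t], xprev)
    }
  }
  merged <- matrix(0, d, T)
  merged_cov <- array(0, c(d, d, T))
  for (t in seq_len(T)) {
    mix <- .mix_gaussians(do.call(cbind, lapply(xs, function(x) x[, t])),
                          lapply(Ps, function(P) P[, , t]), Ws[, t])
    merged[, t] <- mix$mean
    merged_cov[, , t] <- mix$cov
  }
  structure(list(Ws = Ws, pairwise = pairwise, xs = xs, Ps = Ps,
                 x_prev = x_prev, P_prev = P_prev, cross = cross,
                 merged_mean = merged, merged_cov = merged_cov),
            class = "switch_smoother_trace")
}

#' Decode the regime sequence from probability time series
#'
#' Per-time argmax over regimes; exact ties break toward the lowest regime
#' index.
#'
#' @param probs `M x T` matrix of regime probabilities (filtered or
#'   smoothed), or a `switch_filter_trace` / `switch_smoother_trace`.
#' @return length-`T` integer vector of regime labels in `1:M`.
#' @export
decode_regimes <- function(probs) {
  if (inherits(probs, "switch_filter_trace")) probs <- probs$w_filt
  if (inherits(probs, "switch_smoother_trace")) probs <- probs$Ws
  apply(probs, 2, which.max)
}
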