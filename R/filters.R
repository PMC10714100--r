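## Stationary-system inference: the Poisson Cubature Filter (PCF), the
## Laplace-based point-process filter (PPF), and RTS smoothing with the
## cross-covariances needed for EM.
##
## The update functions take likelihood-moment functions (p, q) rather than
## parameter objects, so the same code runs against linear-Gaussian moments
## (where PCF must reproduce the Kalman filter exactly) and against injected
## oracle rules. `run_filter()` dispatches to a compiled fast path for the
## standard Poisson model.

#' Gaussian belief about the latent state
#'
#' @param mean length-`d` mean vector.
#' @param cov `d x d` covariance (symmetrized).
#' @param lag one of `"filtered"` (t|t), `"predicted"` (t|t-1),
#'   `"smoothed"` (t|T).
#' @return object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov, lag = c("filtered", "predicted", "smoothed")) {
  lag <- match.arg(lag)
  structure(list(mean = as.numeric(mean), cov = symmetrize(as.matrix(cov)),
                 lag = lag),
            class = "gaussian_belief")
}

#' Poisson likelihood-moment functions for a parameter set
#'
#' Packages the conditional mean `p(x) = E[n | x]` and covariance
#' `q(x) = V[n | x]` of the Poisson observation model for use by
#' [pcf_update()] and [run_filter()].
#'
#' @param params [plds_params()].
#' @return list of callables `p` (length-`C` vector) and `q` (`C x C`
#'   matrix), plus the parameter set.
#' @export
poisson_moments <- function(params) {
  list(p = function(x) plds_rate(x, params),
       q = function(x) diag(plds_rate(x, params), params$C),
       params = params, kind = "poisson")
}

#' Linear-Gaussian likelihood-moment functions
#'
#' Moments of the surrogate observation model `n = H x + b + v`,
#' `v ~ N(0, R)`. With these moments the PCF update coincides with the
#' Kalman update to floating-point accuracy, because the cubature rule is
#' exact for the degree-2 polynomials involved.
#'
#' @param H observation matrix, `C x d`.
#' @param b length-`C` offset.
#' @param R `C x C` observation noise covariance.
#' @return moment-function list as in [poisson_moments()].
#' @export
gaussian_moments <- function(H, b = rep(0, nrow(H)), R) {
  H <- as.matrix(H); R <- as.matrix(R)
  list(p = function(x) as.vector(H %*% x) + b,
       q = function(x) R,
       H = H, b = b, R = R, kind = "gaussian")
}

#' Kalman-style prediction through the linear dynamics
#'
#' @param belief filtered [gaussian_belief()] at time t-1.
#' @param A dynamics matrix.
#' @param Q state noise covariance.
#' @return predicted belief at time t.
#' @export
predict_belief <- function(belief, A, Q) {
  gaussian_belief(as.vector(A %*% belief$mean),
                  A %*% belief$cov %*% t(A) + Q,
                  lag = "predicted")
}

#' PCF measurement update
#'
#' Minimum mean-squared error update for an estimator linear in the counts.
#' The predictive observation moments are cubature approximations of
#' Gaussian expectations of the likelihood moments over the predicted state
#' density:
#' \deqn{\hat n = \sum_i w_i p(x_i), \quad
#'       \Lambda_{nn} = \sum_i w_i (q(x_i) + p(x_i) p(x_i)^T) - \hat n \hat n^T,
#'       \quad \Lambda_{xn} = \sum_i w_i x_i p(x_i)^T - \hat x \hat n^T}
#' with `x_i` the cubature points of the predicted Gaussian, followed by the
#' MMSE update `x <- x + Λ_xn Λ_nn^{-1} (n - n̂)`. The `Λ_nn` system is
#' solved by Cholesky with escalating diagonal jitter, never by explicit
#' inversion.
#'
#' @param pred predicted [gaussian_belief()].
#' @param n length-`C` observed counts.
#' @param moments moment-function list ([poisson_moments()] or
#'   [gaussian_moments()]).
#' @param rule [cubature_rule()] of matching dimension.
#' @return list with `belief` (filtered) and `diagnostics`
#'   (`n_pred`, `jitter`).
#' @export
pcf_update <- function(pred, n, moments, rule = cubature_rule(length(pred$mean))) {
  d <- length(pred$mean)
  if (rule$d != d) stop("rule dimension does not match belief")
  X <- cubature_points(pred$mean, pred$cov, rule)
  npts <- ncol(X)
  w <- rule$weights
  P <- vapply(seq_len(npts), function(i) moments$p(X[, i]), numeric(length(n)))
  P <- matrix(P, nrow = length(n))
  n_hat <- as.vector(P %*% w)
  Qbar <- matrix(0, length(n), length(n))
  for (i in seq_len(npts)) Qbar <- Qbar + w[i] * moments$q(X[, i])
  Lnn <- Qbar + P %*% (w * t(P)) - tcrossprod(n_hat)
  Lxn <- X %*% (w * t(P)) - tcrossprod(pred$mean, n_hat)
  sol <- psd_solve(symmetrize(Lnn), t(Lxn))   # Lnn^{-1} Lxn'
  K <- t(sol$x)
  mean_new <- pred$mean + as.vector(K %*% (n - n_hat))
  cov_new <- symmetrize(pred$cov - K %*% t(Lxn))
  list(belief = gaussian_belief(mean_new, cov_new, "filtered"),
       diagnostics = list(n_pred = n_hat, jitter = sol$jitter))
}

#' PPF (Laplace) measurement update
#'
#' Approximates the posterior by a Gaussian at the mode of the log posterior
#' `-(x - m)' P^{-1} (x - m) / 2 + sum_i [n_i eta_i - exp(eta_i)]`,
#' `eta_i = alpha_i + beta_i' x`, located by damped Newton iteration started
#' at the prediction (at most `max_iter` iterations, tolerance `tol` on the
#' step norm). The posterior covariance is the inverse curvature at the
#' update point. `one_step = TRUE` gives the classical single-step variant
#' evaluated at the predicted mean.
#'
#' @inheritParams pcf_update
#' @param params [plds_params()].
#' @param one_step use the classical one-Newton-step update.
#' @param max_iter,tol Newton controls.
#' @return filtered [gaussian_belief()].
#' @export
ppf_update <- function(pred, n, params, one_step = FALSE,
                       max_iter = 25, tol = 1e-8) {
  Pinv_m <- psd_solve(pred$cov, cbind(pred$mean))$x
  Pinv <- psd_solve(pred$cov, diag(length(pred$mean)))$x
  beta <- params$beta
  grad <- function(x) {
    r <- plds_rate(x, params)
    as.vector(crossprod(beta, n - r)) - as.vector(Pinv %*% x) + as.vector(Pinv_m)
  }
  info <- function(x) {   # negative Hessian
    r <- plds_rate(x, params)
    Pinv + crossprod(beta, r * beta)
  }
  x <- pred$mean
  if (one_step) {
    J <- info(x)
    x <- x + psd_solve(J, cbind(grad(x)))$x[, 1]
  } else {
    obj <- function(x) {
      r <- plds_rate(x, params)
      dx <- x - pred$mean
      sum(n * log(r) - r) - 0.5 * sum(dx * (Pinv %*% dx))
    }
    f0 <- obj(x)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      step <- psd_solve(info(x), cbind(grad(x)))$x[, 1]
      alpha_ls <- 1
      repeat {
        xn <- x + alpha_ls * step
        if (obj(xn) >= f0 - 1e-12) break
        alpha_ls <- alpha_ls / 2
        if (alpha_ls < 1e-6) { xn <- x; break }
      }
      moved <- sqrt(sum((xn - x)^2))
      x <- xn; f0 <- obj(x)
      if (moved < tol) { converged <- TRUE; break }
    }
    if (!converged && max_iter > 1) {
      warning("ppf_update: Newton did not converge; returning last iterate")
    }
  }
  cov_new <- psd_solve(info(x), diag(length(x)))$x
  gaussian_belief(x, symmetrize(cov_new), "filtered")
}

#' One-step-ahead spike probability
#'
#' `P(n_t^i >= 1 | n_{1:t-1}) = 1 - E[exp(-lambda_i(x) delta)]` under the
#' predicted Gaussian, approximated by cubature.
#'
#' @param pred predicted [gaussian_belief()].
#' @param params [plds_params()].
#' @param rule [cubature_rule()].
#' @return length-`C` vector of probabilities.
#' @export
one_step_spike_prob <- function(pred, params, rule = cubature_rule(length(pred$mean))) {
  X <- cubature_points(pred$mean, pred$cov, rule)
  E <- exp(-exp(pmin(pmax(
    params$alpha + params$beta %*% X, -30), 30)))   # C x npts
  pmin(pmax(1 - as.vector(E %*% rule$weights), 0), 1)
}

#' Run a stationary filter over a spike train
#'
#' Alternates Kalman-style prediction with the PCF or PPF measurement
#' update, starting from the initial belief `N(mu0, Lambda0)`. For the
#' standard Poisson model a compiled fast path is used; supplying `moments`
#' forces the generic R path (e.g. linear-Gaussian surrogates).
#'
#' @param spikes [spike_data()].
#' @param params [plds_params()].
#' @param method `"pcf"` or `"ppf"`.
#' @param rule [cubature_rule()]; defaults to the rule for `params$d`.
#' @param moments optional moment-function list for the generic path.
#' @param spike_probs also compute one-step-ahead spike probabilities.
#' @param loglik also compute the per-step one-step predictive log-likelihood
#'   (cubature-approximated for `"pcf"`-compatible Poisson moments).
#' @param use_cpp use the compiled Poisson fast path when possible.
#' @param one_step classical one-step PPF variant.
#' @return a `filter_trace`: `xf`, `Pf` (filtered means `d x T` and
#'   covariances `d x d x T`), `xp`, `Pp` (predicted), optional `spike_prob`
#'   (`C x T`) and `loglik` (length `T`).
#' @export
run_filter <- function(spikes, params, method = c("pcf", "ppf"),
                       rule = cubature_rule(params$d), moments = NULL,
                       spike_probs = FALSE, loglik = FALSE,
                       use_cpp = TRUE, one_step = FALSE) {
  method <- match.arg(method)
  counts <- spikes$counts
  d <- params$d; T <- ncol(counts)
  if (T == 0) {
    return(structure(list(xf = matrix(0, d, 0), Pf = array(0, c(d, d, 0)),
                          xp = matrix(0, d, 0), Pp = array(0, c(d, d, 0)),
                          method = method), class = "filter_trace"))
  }
  if (is.null(moments) && use_cpp) {
    out <- plds_filter_cpp(counts, params$A, params$Q, params$mu0,
                           params$Lambda0, params$alpha, params$beta,
                           rule$points, rule$weights,
                           method == "ppf", one_step, spike_probs, loglik)
    if (!is.null(out$loglik)) out$loglik <- as.vector(out$loglik)
    out$method <- method
    return(structure(out, class = "filter_trace"))
  }
  if (is.null(moments)) moments <- poisson_moments(params)
  xf <- matrix(0, d, T); xp <- matrix(0, d, T)
  Pf <- array(0, c(d, d, T)); Pp <- array(0, c(d, d, T))
  sp <- if (spike_probs) matrix(0, params$C, T) else NULL
  ll <- if (loglik) numeric(T) else NULL
  bel <- gaussian_belief(params$mu0, params$Lambda0, "filtered")
  for (t in seq_len(T)) {
    pred <- predict_belief(bel, params$A, params$Q)
    xp[, t] <- pred$mean; Pp[, , t] <- pred$cov
    if (spike_probs) sp[, t] <- one_step_spike_prob(pred, params, rule)
    if (loglik) ll[t] <- predictive_log_likelihood(pred, counts[, t], params, rule)
    bel <- if (method == "pcf") {
      pcf_update(pred, counts[, t], moments, rule)$belief
    } else {
      ppf_update(pred, counts[, t], params, one_step = one_step)
    }
    xf[, t] <- bel$mean; Pf[, , t] <- bel$cov
  }
  structure(list(xf = xf, Pf = Pf, xp = xp, Pp = Pp, spike_prob = sp,
                 loglik = ll, method = method),
            class = "filter_trace")
}

#' One-step predictive log-likelihood of a bin of counts
#'
#' `log E_x[P(n_t | x)]` under the predicted Gaussian, approximated by
#' cubature with a max-shift for stability.
#'
#' @param pred predicted [gaussian_belief()].
#' @param n observed counts for one bin.
#' @param params [plds_params()].
#' @param rule [cubature_rule()].
#' @return scalar log predictive likelihood.
#' @export
predictive_log_likelihood <- function(pred, n, params,
                                      rule = cubature_rule(length(pred$mean))) {
  X <- cubature_points(pred$mean, pred$cov, rule)
  ll <- vapply(seq_len(ncol(X)), function(i)
    plds_log_likelihood(n, X[, i], params), numeric(1))
  m <- max(ll)
  s <- sum(rule$weights * exp(ll - m))
  if (s <= 0) return(plds_log_likelihood(n, pred$mean, params))
  m + log(s)
}

#' RTS smoothing with EM cross-covariances
#'
#' Standard backward recursion over a completed [run_filter()] trace.
#' Also returns the time-0 smoothed belief (the prior state) and the
#' pairwise cross-moments `E[x_t x_{t-1}' | n_{1:T}]` that the EM dynamics
#' update needs.
#'
#' @param trace a `filter_trace`.
#' @param A,Q dynamics parameters used to produce the trace.
#' @param mu0,Lambda0 prior state mean and covariance (for the time-0 pass).
#' @param use_cpp use the compiled backward pass.
#' @return a `smoother_trace`: `xs`, `Ps` (smoothed, `d x T`, `d x d x T`),
#'   `x0`, `P0` (smoothed prior state) and `cross` (`d x d x T`,
#'   `cross[,,t] = E[x_t x_{t-1}' | n_{1:T}]` with `x_0` the prior state).
#' @export
rts_smooth <- function(trace, A, Q, mu0 = NULL, Lambda0 = NULL, use_cpp = TRUE) {
  T <- ncol(trace$xf)
  d <- nrow(trace$xf)
  if (use_cpp) {
    out <- rts_smooth_cpp(trace$xf, trace$Pf, trace$xp, trace$Pp, as.matrix(A),
                          if (is.null(mu0)) numeric(0) else as.numeric(mu0),
                          if (is.null(Lambda0)) matrix(0, 0, 0) else as.matrix(Lambda0))
    if (!is.null(out$x0)) out$x0 <- as.vector(out$x0)
    return(structure(out, class = "smoother_trace"))
  }
  xs <- trace$xf; Ps <- trace$Pf
  cross <- array(0, c(d, d, T))
  if (T > 1) {
    for (t in (T - 1):1) {
      G <- t(psd_solve(trace$Pp[, , t + 1],
                       A %*% trace$Pf[, , t])$x)    # Pf A' Pp^{-1}
      xs[, t] <- trace$xf[, t] + G %*% (xs[, t + 1] - trace$xp[, t + 1])
      Ps[, , t] <- symmetrize(trace$Pf[, , t] +
        G %*% (Ps[, , t + 1] - trace$Pp[, , t + 1]) %*% t(G))
      cross[, , t + 1] <- Ps[, , t + 1] %*% t(G) + tcrossprod(xs[, t + 1], xs[, t])
    }
  }
  out <- list(xs = xs, Ps = Ps, cross = cross)
  if (!is.null(mu0)) {
    G0 <- t(psd_solve(trace$Pp[, , 1], A %*% Lambda0)$x)
    out$x0 <- as.numeric(mu0 + G0 %*% (xs[, 1] - trace$xp[, 1]))
    out$P0 <- symmetrize(Lambda0 + G0 %*% (Ps[, , 1] - trace$Pp[, , 1]) %*% t(G0))
    cross[, , 1] <- Ps[, , 1] %*% t(G0) + tcrossprod(xs[, 1], out$x0)
    out$cross <- cross
  }
  structure(out, class = "smoother_trace")
}
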