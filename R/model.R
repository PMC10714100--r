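## Poisson linear dynamical system (PLDS) parameter containers, the Poisson
## likelihood moment functions, and JSON serialization.

#' Construct stationary Poisson-LDS parameters
#'
#' The model is a latent linear-Gaussian random walk observed through
#' conditionally independent Poisson counts with a log-link rate:
#' \deqn{x_t = A x_{t-1} + w_t, \quad w_t \sim N(0, Q)}
#' \deqn{n_t^i \sim \mathrm{Poisson}(\lambda_i(x_t) \Delta), \quad
#'       \lambda_i(x_t)\Delta = \exp(\alpha_i + \beta_i^T x_t).}
#'
#' @param A `d x d` dynamics matrix.
#' @param Q `d x d` symmetric PSD state-noise covariance.
#' @param mu0 length-`d` initial state mean.
#' @param Lambda0 `d x d` initial state covariance.
#' @param alpha length-`C` baseline log expected counts per bin.
#' @param beta `C x d` encoding matrix; row i is the direction for neuron i.
#' @param delta bin width in seconds (> 0).
#' @return an object of class `plds_params`.
#' @export
plds_params <- function(A, Q, mu0, Lambda0, alpha, beta, delta) {
  A <- as.matrix(A); Q <- symmetrize(as.matrix(Q))
  beta <- as.matrix(beta); Lambda0 <- symmetrize(as.matrix(Lambda0))
  d <- nrow(A)
  stopifnot(ncol(A) == d, all(dim(Q) == d), length(mu0) == d,
            all(dim(Lambda0) == d), ncol(beta) == d,
            length(alpha) == nrow(beta), length(delta) == 1, delta > 0)
  structure(list(A = A, Q = Q, mu0 = as.numeric(mu0), Lambda0 = Lambda0,
                 alpha = as.numeric(alpha), beta = beta, delta = delta,
                 d = d, C = length(alpha)),
            class = "plds_params")
}

#' @export
print.plds_params <- function(x, ...) {
  cat(sprintf("Poisson LDS: d = %d latent dims, C = %d neurons, delta = %g s\n",
              x$d, x$C, x$delta))
  invisible(x)
}

#' Construct switching Poisson-LDS parameters
#'
#' A first-order Markov regime state `s_t` selects which of `M` stationary
#' parameter sets is active at each bin. The transition matrix is
#' column-stochastic: `Phi[j, i] = P(s_t = j | s_{t-1} = i)`.
#'
#' @param regimes list of `M` [plds_params()] sharing `d`, `C` and `delta`.
#' @param Phi `M x M` column-stochastic regime transition matrix.
#' @param pi length-`M` initial regime distribution.
#' @return an object of class `switching_plds_params`.
#' @export
switching_plds_params <- function(regimes, Phi, pi = rep(1 / length(regimes), length(regimes))) {
  M <- length(regimes)
  Phi <- as.matrix(Phi)
  stopifnot(M >= 1, all(dim(Phi) == M), length(pi) == M)
  if (any(Phi < -1e-12) || any(abs(colSums(Phi) - 1) > 1e-8)) {
    stop("Phi must be column-stochastic: Phi[j, i] = P(s_t = j | s_{t-1} = i)")
  }
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  d <- regimes[[1]]$d; C <- regimes[[1]]$C; delta <- regimes[[1]]$delta
  for (r in regimes) stopifnot(r$d == d, r$C == C, r$delta == delta)
  structure(list(regimes = regimes, Phi = Phi, pi = as.numeric(pi),
                 M = M, d = d, C = C, delta = delta),
            class = "switching_plds_params")
}

#' @export
print.switching_plds_params <- function(x, ...) {
  cat(sprintf("Switching Poisson LDS: M = %d regimes, d = %d, C = %d, delta = %g s\n",
              x$M, x$d, x$C, x$delta))
  invisible(x)
}

#' Spike-count container
#'
#' @param counts `C x T` matrix of nonnegative integer counts (neurons in
#'   rows, time bins in columns).
#' @param delta bin width in seconds.
#' @return an object of class `spike_data`.
#' @export
spike_data <- function(counts, delta) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  stopifnot(delta > 0)
  structure(list(counts = counts, delta = delta,
                 C = nrow(counts), T = ncol(counts)),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d neurons x %d bins (delta = %g s, mean count %.4g)\n",
              x$C, x$T, x$delta, mean(x$counts)))
  invisible(x)
}

# exponent clip bound for the log-link; counts of clipping events are kept so
# callers can report when early EM iterations hit badly scaled parameters
.clip_env <- new.env(parent = emptyenv())
.clip_env$count <- 0L

#' Number of rate-exponent clipping events so far
#' @return integer count of times the log-rate exponent was clipped.
#' @export
rate_clip_count <- function() .clip_env$count

#' Expected spike count per bin (the rate function)
#'
#' `rate(x, params)[i] = exp(alpha_i + beta_i' x) = lambda_i(x) * delta`,
#' the expected count of neuron i in one bin of width delta. The exponent is
#' clipped to \[-30, 30\] to guard against overflow with badly scaled
#' parameters; clip events are counted (see [rate_clip_count()]).
#'
#' @param x length-`d` latent state.
#' @param params [plds_params()].
#' @return length-`C` positive vector of expected counts per bin.
#' @export
plds_rate <- function(x, params) {
  eta <- params$alpha + as.vector(params$beta %*% x)
  bad <- abs(eta) > 30
  if (any(bad)) {
    .clip_env$count <- .clip_env$count + sum(bad)
    eta <- pmin(pmax(eta, -30), 30)
  }
  exp(eta)
}

#' Likelihood mean and variance of the Poisson observation
#'
#' Returns `p(x) = E[n_t | x_t = x]` and the diagonal of
#' `q(x) = V[n_t | x_t = x]`; for Poisson counts the two are equal
#' elementwise and neurons are conditionally independent, so `q` is diagonal.
#'
#' @inheritParams plds_rate
#' @return list with `p` (length-`C`) and `q_diag` (length-`C`).
#' @export
likelihood_moments <- function(x, params) {
  r <- plds_rate(x, params)
  list(p = r, q_diag = r)
}

#' Poisson log-likelihood of one bin of counts
#'
#' @param n length-`C` nonnegative integer counts.
#' @inheritParams plds_rate
#' @return scalar `sum_i [n_i log(r_i) - r_i - log(n_i!)]` where
#'   `r_i = lambda_i(x) delta`.
#' @export
plds_log_likelihood <- function(n, x, params) {
  stopifnot(length(n) == params$C, all(n >= 0))
  r <- plds_rate(x, params)
  sum(stats::dpois(n, r, log = TRUE))
}

## ---- serialization ---------------------------------------------------------

#' Write model parameters to JSON
#'
#' Stationary and switching parameter sets serialize to a single
#' schema-versioned JSON document (scalars and nested arrays).
#'
#' @param params [plds_params()] or [switching_plds_params()].
#' @param path file path to write.
#' @export
write_params_json <- function(params, path) {
  to_plain <- function(p) list(A = p$A, Q = p$Q, mu0 = p$mu0,
                               Lambda0 = p$Lambda0, alpha = p$alpha,
                               beta = p$beta, delta = p$delta)
  obj <- if (inherits(params, "plds_params")) {
    list(schema = "pcfilter-params", version = 1L, kind = "stationary",
         params = to_plain(params))
  } else if (inherits(params, "switching_plds_params")) {
    list(schema = "pcfilter-params", version = 1L, kind = "switching",
         Phi = params$Phi, pi = params$pi,
         regimes = lapply(params$regimes, to_plain))
  } else stop("unsupported parameter object")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path file written by [write_params_json()].
#' @return [plds_params()] or [switching_plds_params()].
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "pcfilter-params")) stop("not a pcfilter parameter file")
  from_plain <- function(p) plds_params(
    A = p$A, Q = p$Q, mu0 = p$mu0, Lambda0 = p$Lambda0,
    alpha = p$alpha, beta = p$beta, delta = p$delta)
  if (identical(obj$kind, "stationary")) return(from_plain(obj$params))
  switching_plds_params(lapply(obj$regimes, from_plain), obj$Phi, obj$pi)
}
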