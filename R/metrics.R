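## Evaluation protocol: neural self-prediction (predictive power), regime
## decoding accuracy with label matching, similarity-aligned latent
## correlation, normalized parameter and eigenvalue errors, and behavior
## decoding.

# rank-statistic AUC with ties counted as half-wins
.auc_rank <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Neural self-prediction (predictive power)
#'
#' Binarizes counts as spike / no-spike (`n >= 1`), computes the per-neuron
#' ROC AUC of the one-step-ahead spike probabilities against the events
#' (rank statistic, ties as half-wins), averages AUC across neurons, and
#' returns `PP = 2 AUC - 1` (0 = chance, 1 = perfect). Neurons whose events
#' are all zero or all one are excluded; their count is attached as
#' attribute `n_excluded`.
#'
#' @param probs `C x T` one-step-ahead spike probabilities
#'   (from [run_filter()] or [run_switching_filter()] with
#'   `spike_probs = TRUE`).
#' @param spikes matching [spike_data()].
#' @return scalar predictive power in `[-1, 1]`.
#' @export
predictive_power <- function(probs, spikes) {
  counts <- spikes$counts
  stopifnot(all(dim(probs) == dim(counts)))
  aucs <- vapply(seq_len(nrow(counts)), function(i)
    .auc_rank(probs[i, ], counts[i, ] >= 1), numeric(1))
  keep <- !is.na(aucs)
  if (!any(keep)) stop("all neurons degenerate; predictive power undefined")
  out <- 2 * mean(aucs[keep]) - 1
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Mixture one-step-ahead spike probabilities for a switching model
#'
#' Regime-weighted mixture of per-regime one-step spike probabilities with
#' weights given by the one-step-ahead regime prediction
#' `Phi %*% P(s_{t-1} | n_{1:t-1})`. Provided by the switching filter
#' directly; this helper re-runs the filter when the trace lacks them.
#'
#' @param spikes [spike_data()].
#' @param params [switching_plds_params()].
#' @param method base filter for decoding (`"ppf"` by default, matching the
#'   evaluation-time decoder convention).
#' @param rule [cubature_rule()].
#' @return `C x T` probability matrix.
#' @export
switching_spike_prob <- function(spikes, params, method = "ppf",
                                 rule = cubature_rule(params$d)) {
  tr <- run_switching_filter(spikes, params, method = method, rule = rule,
                             spike_probs = TRUE)
  tr$spike_prob
}

#' Regime decoding accuracy with label matching
#'
#' Proportion of time bins where decoded and true regimes agree, maximized
#' over all `M!` label permutations (unsupervised learning only recovers
#' regimes up to relabeling).
#'
#' @param true_s,decoded_s integer regime sequences of equal length.
#' @param M number of regimes (at most 8; the factorial search is refused
#'   beyond that).
#' @return list with `acc` and the maximizing `permutation` (decoded label
#'   `j` is interpreted as true label `permutation[j]`).
#' @export
regime_accuracy <- function(true_s, decoded_s, M) {
  stopifnot(length(true_s) == length(decoded_s))
  if (M > 8) stop("permutation search refused for M > 8")
  best <- -1; best_p <- seq_len(M)
  for (p in permutations(M)) {
    acc <- mean(p[decoded_s] == true_s)
    if (acc > best) { best <- acc; best_p <- p }
  }
  list(acc = best, permutation = best_p)
}

#' Normalize a decoding metric against its true-parameter baseline
#'
#' `pp` and `cc` kinds return `value / true_value`; `acc` subtracts chance
#' `1/M` from both before the ratio, so 0 is chance and 1 is true-parameter
#' performance.
#'
#' @param value metric with learned parameters.
#' @param true_value same metric with ground-truth parameters.
#' @param kind `"pp"`, `"cc"` or `"acc"`.
#' @param M number of regimes (required for `"acc"`).
#' @return normalized metric.
#' @export
normalized_metric <- function(value, true_value, kind = c("pp", "cc", "acc"),
                              M = NULL) {
  kind <- match.arg(kind)
  if (kind == "acc") {
    stopifnot(!is.null(M))
    den <- true_value - 1 / M
    if (abs(den) < 1e-12) stop("undefined normalized accuracy: true accuracy at chance")
    return((value - 1 / M) / den)
  }
  if (abs(true_value) < 1e-12) stop("undefined normalized metric: zero baseline")
  value / true_value
}

#' Fit the latent similarity transform
#'
#' Least-squares `L = argmin sum_t |L xhat_learn - xhat_true|^2
#' = Xtrue Xlearn^+`, aligning the learned model's latent basis with the
#' true one using one-step predicted latents on a shared calibration
#' sequence.
#'
#' @param pred_true,pred_learn `d x q` matrices of one-step predicted
#'   latents under the true and learned models.
#' @return list with `L` (`d x d`) and `q` (calibration sample count).
#' @export
fit_similarity_transform <- function(pred_true, pred_learn) {
  stopifnot(all(dim(pred_true) == dim(pred_learn)))
  sv <- svd(pred_learn)
  tol <- max(dim(pred_learn)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  if (!all(pos)) warning("rank-deficient learned predictions; minimum-norm transform")
  pinv <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(L = pred_true %*% pinv, q = ncol(pred_true))
}

#' Average latent correlation after similarity alignment
#'
#' Per-dimension Pearson correlation of `L %*% decoded` against the true
#' latents, averaged over dimensions; zero-variance dimensions are excluded
#' with a warning.
#'
#' @param decoded,true `d x T` latent matrices.
#' @param L similarity transform applied to `decoded`.
#' @return average correlation coefficient.
#' @export
latent_cc <- function(decoded, true, L = diag(nrow(decoded))) {
  Z <- L %*% decoded
  ccs <- vapply(seq_len(nrow(true)), function(i) {
    if (stats::sd(Z[i, ]) < 1e-12 || stats::sd(true[i, ]) < 1e-12) return(NA_real_)
    stats::cor(Z[i, ], true[i, ])
  }, numeric(1))
  if (any(is.na(ccs))) warning(sum(is.na(ccs)), " zero-variance dimension(s) excluded")
  mean(ccs, na.rm = TRUE)
}

#' Normalized parameter and eigenvalue errors
#'
#' Re-expresses the learned parameters in the true basis through the
#' similarity transform (`A -> L A L^{-1}`, `Q -> L Q L'`,
#' `beta -> beta L^{-1}`, `mu0 -> L mu0`, `Lambda0 -> L Lambda0 L'`) and
#' reports the normalized Frobenius error per parameter plus the normalized
#' eigenvalue error `sum |eig_learn - eig_true| / sum |eig_true|` with
#' eigenvalues matched by the minimal-total-error assignment.
#'
#' @param learned,true [plds_params()].
#' @param L similarity transform from [fit_similarity_transform()].
#' @return named list of errors `A`, `Q`, `alpha`, `beta`, `mu0`,
#'   `Lambda0`, `eig`.
#' @export
parameter_errors <- function(learned, true, L) {
  if (abs(det(L)) < 1e-12) stop("singular similarity transform")
  Li <- solve(L)
  tr <- list(A = L %*% learned$A %*% Li,
             Q = L %*% learned$Q %*% t(L),
             alpha = learned$alpha,
             beta = learned$beta %*% Li,
             mu0 = L %*% cbind(learned$mu0),
             Lambda0 = L %*% learned$Lambda0 %*% t(L))
  ref <- list(A = true$A, Q = true$Q, alpha = true$alpha, beta = true$beta,
              mu0 = cbind(true$mu0), Lambda0 = true$Lambda0)
  fe <- function(a, b) {
    nb <- sqrt(sum(b^2)); nd <- sqrt(sum((a - b)^2))
    if (nb == 0) return(if (nd == 0) 0 else Inf)   # zero reference parameter
    nd / nb
  }
  errs <- lapply(names(ref), function(nm) fe(tr[[nm]], ref[[nm]]))
  names(errs) <- names(ref)
  errs$eig <- eigenvalue_error(eigen(learned$A)$values, eigen(true$A)$values)
  errs
}

#' Normalized eigenvalue error with optimal matching
#'
#' `sum_i |eig_learn_(i) - eig_true_i| / sum_i |eig_true_i|` minimized over
#' assignments of learned to true eigenvalues (full permutation search,
#' d <= 8).
#'
#' @param eig_learn,eig_true complex eigenvalue vectors of equal length.
#' @return normalized eigenvalue error.
#' @export
eigenvalue_error <- function(eig_learn, eig_true) {
  d <- length(eig_true)
  stopifnot(length(eig_learn) == d)
  if (d > 8) stop("assignment search refused for d > 8")
  denom <- sum(Mod(eig_true))
  best <- Inf
  for (p in permutations(d)) {
    err <- sum(Mod(eig_learn[p] - eig_true))
    if (err < best) best <- err
  }
  best / denom
}

#' Linear behavior decoding from latent states
#'
#' Ordinary least squares with intercept mapping training latents to
#' behavior, applied to test latents; per-dimension Pearson correlation on
#' the test set (when test behavior is supplied), averaged.
#'
#' @param latents_train `d x T1` training latents.
#' @param behavior_train `k x T1` training behavior.
#' @param latents_test `d x T2` test latents.
#' @param behavior_test optional `k x T2` test behavior for the CC.
#' @return list with `predicted` (`k x T2`), `W`, `intercept`, and `cc`
#'   (NA without test behavior).
#' @export
behavior_decode <- function(latents_train, behavior_train, latents_test,
                            behavior_test = NULL) {
  X <- cbind(1, t(latents_train))
  Y <- t(behavior_train)
  fit <- tryCatch(qr.solve(X, Y), error = function(e) {
    warning("rank-deficient latents; minimum-norm behavior fit")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d)
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]) %*% Y
  })
  pred <- t(cbind(1, t(latents_test)) %*% fit)
  cc <- NA_real_
  if (!is.null(behavior_test)) {
    ccs <- vapply(seq_len(nrow(pred)), function(i) {
      if (stats::sd(pred[i, ]) < 1e-12) return(0)
      stats::cor(pred[i, ], behavior_test[i, ])
    }, numeric(1))
    cc <- mean(ccs)
  }
  list(predicted = pred, W = t(fit[-1, , drop = FALSE]),
       intercept = fit[1, ], cc = cc)
}
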