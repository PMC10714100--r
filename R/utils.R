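## Internal numerical helpers shared across the filters and EM code.

#' @keywords internal
symmetrize <- function(M) (M + t(M)) / 2

#' Lower-triangular matrix square root with an eigendecomposition fallback
#'
#' Cholesky is attempted first; if the matrix is numerically indefinite the
#' symmetric eigendecomposition is used with negative eigenvalues clipped at
#' zero, so that long EM runs survive marginally indefinite covariances.
#'
#' @param S symmetric positive-semidefinite matrix.
#' @param warn emit a warning when the eigendecomposition fallback triggers.
#' @return lower-triangular (Cholesky case) or general square root `L` with
#'   `L %*% t(L) == S` up to clipping.
#' @keywords internal
mat_sqrt <- function(S, warn = TRUE) {
  S <- symmetrize(as.matrix(S))
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  if (warn) warning("covariance not positive definite; eigenvalue-clipped square root used")
  ee$vectors %*% (sqrt(vals) * t(ee$vectors))
}

## Symmetric positive-definite solve with escalating diagonal jitter.
## Jitter starts at 1e-10 * mean diagonal scale and grows tenfold up to 1e-4.
#' @keywords internal
psd_solve <- function(S, B, jitter_start = 1e-10, jitter_max = 1e-4) {
  S <- symmetrize(S)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 0
  repeat {
    R <- tryCatch(chol(S + diag(jit * scale, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(x = backsolve(R, forwardsolve(t(R), B)), jitter = jit))
    }
    jit <- if (jit == 0) jitter_start else jit * 10
    if (jit > jitter_max) break
  }
  # last resort for badly indefinite matrices: eigenvalue-clipped solve
  if (any(!is.finite(S))) stop("non-finite matrix in symmetric solve")
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 1e-10 * scale)
  list(x = ee$vectors %*% ((t(ee$vectors) %*% B) / vals), jitter = Inf)
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Stationary covariance of x_t = A x_{t-1} + w_t, w ~ N(0, Q):
## solves the discrete Lyapunov equation S = A S A' + Q by the vec identity.
#' @keywords internal
dlyap <- function(A, Q) {
  d <- nrow(A)
  S <- solve(diag(d * d) - kronecker(A, A), as.vector(Q))
  symmetrize(matrix(S, d, d))
}

## All permutations of 1:n as a list (n <= 8 guarded by callers).
#' @keywords internal
permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
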