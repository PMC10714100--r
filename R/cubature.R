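## 5th-degree spherical-radial cubature rule and Gaussian expectations.

# rules are deterministic, so cache them per dimension
.rule_cache <- new.env(parent = emptyenv())

#' Generate the 5th-degree spherical-radial cubature rule
#'
#' Produces the deterministic weights and unit points that integrate
#' polynomials of total degree up to 5 exactly against a standard normal in
#' `d` dimensions using `2 d^2 + 1` points: one central point, `2d` axial
#' points at `±sqrt(d + 2) e_j`, and `2 d (d - 1)` cross points at
#' `±sqrt(d + 2) (e_k ± e_l) / sqrt(2)` for `k < l`.
#'
#' Weights are `2 / (d + 2)` for the central point,
#' `(4 - d) / (2 (d + 2)^2)` for axial points and `1 / (d + 2)^2` for cross
#' points; they sum to one but individual weights may be zero (axial weights
#' vanish at `d = 4`) or negative (`d > 4`).
#'
#' @param d positive integer dimension.
#' @return an object of class `cubature_rule` with fields `d`,
#'   `weights` (length `2 d^2 + 1`) and `points` (`d x (2 d^2 + 1)` matrix,
#'   one unit point per column).
#' @examples
#' r <- cubature_rule(3)
#' sum(r$weights)          # 1
#' ncol(r$points)          # 19
#' @export
cubature_rule <- function(d) {
  if (length(d) != 1 || !is.finite(d) || d < 1 || d != round(d)) {
    stop("d must be a single integer >= 1")
  }
  d <- as.integer(d)
  key <- as.character(d)
  if (!is.null(.rule_cache[[key]])) return(.rule_cache[[key]])

  n <- 2L * d * d + 1L
  s <- sqrt(d + 2)
  pts <- matrix(0, d, n)
  w <- numeric(n)
  w[1] <- 2 / (d + 2)
  # axial points +/- sqrt(d+2) e_j
  idx <- 2L
  for (j in seq_len(d)) {
    pts[j, idx] <- s; pts[j, idx + 1L] <- -s
    idx <- idx + 2L
  }
  w[2:(2L * d + 1L)] <- (4 - d) / (2 * (d + 2)^2)
  # cross points +/- sqrt(d+2)(e_k +/- e_l)/sqrt(2), k < l
  if (d >= 2) {
    for (k in seq_len(d - 1L)) {
      for (l in (k + 1L):d) {
        v <- numeric(d)
        v[k] <- s / sqrt(2); v[l] <- s / sqrt(2)
        u <- numeric(d)
        u[k] <- s / sqrt(2); u[l] <- -s / sqrt(2)
        pts[, idx] <- v; pts[, idx + 1L] <- -v
        pts[, idx + 2L] <- u; pts[, idx + 3L] <- -u
        idx <- idx + 4L
      }
    }
    w[(2L * d + 2L):n] <- 1 / (d + 2)^2
  }
  rule <- structure(list(d = d, weights = w, points = pts),
                    class = "cubature_rule")
  .rule_cache[[key]] <- rule
  rule
}

#' @export
print.cubature_rule <- function(x, ...) {
  cat(sprintf("5th-degree spherical-radial cubature rule: d = %d, %d points\n",
              x$d, length(x$weights)))
  invisible(x)
}

#' Cubature points for a general Gaussian
#'
#' Affinely maps the unit points of a rule to `mean + sqrt(cov) xi_i`.
#'
#' @param mean length-`d` mean vector.
#' @param cov `d x d` symmetric PSD covariance.
#' @param rule a [cubature_rule()] of matching dimension.
#' @return `d x (2 d^2 + 1)` matrix of evaluation points.
#' @export
cubature_points <- function(mean, cov, rule = cubature_rule(length(mean))) {
  if (rule$d != length(mean)) stop("rule dimension does not match mean length")
  L <- mat_sqrt(cov)
  sweep(L %*% rule$points, 1, mean, `+`)
}

#' Approximate a Gaussian expectation with a cubature rule
#'
#' Computes `sum_i w_i g(mean + sqrt(cov) xi_i)`, which is exact for
#' polynomial `g` of total degree at most 5. `g` may return a vector; it is
#' applied column-wise to the evaluation points.
#'
#' @param g function of a length-`d` vector returning a numeric vector.
#' @param mean,cov Gaussian mean and covariance.
#' @param rule a [cubature_rule()]; any object with `d`, `weights`, `points`
#'   fields works, so a quadrature oracle can be injected in tests.
#' @return the approximated expectation `E[g(X)]`.
#' @examples
#' gaussian_expectation(function(x) exp(x), 0.3, matrix(0.04), cubature_rule(1))
#' @export
gaussian_expectation <- function(g, mean, cov, rule = cubature_rule(length(mean))) {
  X <- cubature_points(mean, as.matrix(cov), rule)
  vals <- apply(X, 2, g)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  as.vector(vals %*% rule$weights)
}
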