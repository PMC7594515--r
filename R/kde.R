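#' Scott bandwidths for kernel density estimation
#'
#' `bandwidth_scott()` returns the univariate Scott-rule bandwidth
#' \eqn{h = s \, n^{-1/5}} (standard deviation units). `bandwidth_scott_2d()`
#' returns the diagonal bivariate bandwidth matrix with
#' \eqn{H_{kk} = (s_k \, n^{-1/6})^2}, the squared per-dimension Scott
#' bandwidth. Both are scale-equivariant smooth defaults; the joint
#' estimator accepts any symmetric positive-definite `H` if you want to
#' supply your own.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param xy Numeric matrix (or data frame) with two non-degenerate columns.
#' @return A positive scalar, or a symmetric positive-definite 2 x 2 matrix.
#' @examples
#' bandwidth_scott(rnorm(100))
#' bandwidth_scott_2d(cbind(rnorm(64), rnorm(64)))
#' @export
bandwidth_scott <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) abort("Need at least 2 observations for a bandwidth.")
  s <- sd(x)
  if (!is.finite(s) || s <= 0) abort("degenerate node: zero variance.")
  s * n^(-1 / 5)
}

#' @rdname bandwidth_scott
#' @export
bandwidth_scott_2d <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) abort("`xy` must have exactly two columns.")
  n <- nrow(xy)
  if (n < 2L) abort("Need at least 2 observations for a bandwidth.")
  s <- apply(xy, 2L, sd)
  if (any(!is.finite(s) | s <= 0)) abort("degenerate node: zero variance.")
  diag((s * n^(-1 / 6))^2)
}

check_bandwidth_matrix <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == 2L) || max(abs(H - t(H))) > 1e-12) {
    abort("Bandwidth matrix `H` must be symmetric 2 x 2.")
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("Bandwidth matrix `H` must be positive definite.")
  H
}

#' Univariate normal-kernel density estimate
#'
#' Exact kernel sum \eqn{\hat f(q) = n^{-1} \sum_i \phi((q - x_i)/h)/h}
#' with the normal kernel, evaluated at each query point.
#'
#' @param sample Numeric vector of observations.
#' @param query Numeric vector of evaluation points.
#' @param h Positive bandwidth (defaults to [bandwidth_scott()]).
#' @return Numeric vector of positive densities, one per query point.
#' @examples
#' kde_density(rnorm(50), query = c(-1, 0, 1))
#' @export
kde_density <- function(sample, query, h = bandwidth_scott(sample)) {
  sample <- as.numeric(sample)
  query <- as.numeric(query)
  if (length(sample) < 1L) abort("`sample` is empty.")
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    abort("Bandwidth `h` must be a positive scalar.")
  }
  k <- exp(-outer(query, sample, "-")^2 / (2 * h^2))
  rowMeans(k) / (h * sqrt(2 * pi))
}

#' Bivariate normal-kernel density estimate
#'
#' Exact kernel sum over all observations,
#' \eqn{\hat f(z) = n^{-1} \sum_i (2\pi)^{-1} |H|^{-1/2}
#' \exp(-\tfrac12 (z - Z_i)^T H^{-1} (z - Z_i))},
#' with a bivariate normal kernel and symmetric positive-definite bandwidth
#' matrix `H`.
#'
#' @param sample Numeric n x 2 matrix of observations.
#' @param query Numeric m x 2 matrix of evaluation points.
#' @param H Symmetric positive-definite 2 x 2 bandwidth matrix (defaults to
#'   [bandwidth_scott_2d()]).
#' @return Numeric vector of positive densities, one per query row.
#' @examples
#' z <- cbind(rnorm(100), rnorm(100))
#' bkde_density(z, query = rbind(c(0, 0), c(1, 1)))
#' @export
bkde_density <- function(sample, query, H = bandwidth_scott_2d(sample)) {
  sample <- as.matrix(sample)
  query <- as.matrix(query)
  if (ncol(sample) != 2L || ncol(query) != 2L) {
    abort("`sample` and `query` must each have two columns.")
  }
  if (nrow(sample) < 1L) abort("`sample` is empty.")
  H <- check_bandwidth_matrix(H)
  Hinv <- solve(H)
  dx <- outer(query[, 1L], sample[, 1L], "-")
  dy <- outer(query[, 2L], sample[, 2L], "-")
  q <- Hinv[1L, 1L] * dx^2 + 2 * Hinv[1L, 2L] * dx * dy + Hinv[2L, 2L] * dy^2
  const <- 1 / (2 * pi * sqrt(det(H)))
  rowMeans(exp(-q / 2)) * const
}
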