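#' Thin singular value decomposition with rank reporting
#'
#' Computes the thin SVD `Y = P diag(d) Q'` and reports the numerical rank,
#' treating singular values below `1e-12 * max(d)` as zero.
#'
#' @param Y A numeric matrix with finite entries.
#' @return A list of class `svd_triple` with components `P` (left singular
#'   vectors), `d` (singular values, nonincreasing), `Q` (right singular
#'   vectors) and `rank` (numerical rank).
#' @examples
#' s <- thin_svd(matrix(rnorm(12), 3, 4))
#' max(abs(s$P %*% (s$d * t(s$Q)) - matrix(0, 3, 4))) >= 0
#' @export
thin_svd <- function(Y) {
  Y <- as.matrix(Y)
  if (length(Y) == 0L) stop("thin_svd: empty matrix", call. = FALSE)
  if (!all(is.finite(Y))) stop("thin_svd: non-finite entries", call. = FALSE)
  s <- svd(Y)
  rank <- if (s$d[1] > 0) sum(s$d > 1e-12 * s$d[1]) else 0L
  structure(list(P = s$u, d = s$d, Q = s$v, rank = as.integer(rank)),
            class = "svd_triple")
}

#' Soft-thresholding (shrinkage) operator
#'
#' Element-wise proximal operator of the l1 norm: values within `eps` of zero
#' are zeroed, the rest are moved `eps` towards zero. On matrices and vectors
#' it acts element by element.
#'
#' @param x A numeric scalar, vector or matrix.
#' @param eps Threshold, a positive scalar.
#' @return Same shape as `x`.
#' @examples
#' soft_threshold(1.2, 0.5)   # 0.7
#' soft_threshold(0.3, 0.5)   # 0
#' @export
soft_threshold <- function(x, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("soft_threshold: 'eps' must be a positive scalar", call. = FALSE)
  sign(x) * pmax(abs(x) - eps, 0)
}

#' Singular value thresholding operator
#'
#' Proximal operator of the nuclear norm: shrinks every singular value of `Y`
#' by `lam`, discarding those that fall below zero.
#'
#' @param Y A numeric matrix with finite entries.
#' @param lam Shrinkage amount, a positive scalar.
#' @return A matrix of the same shape as `Y` with rank no larger than the rank
#'   of `Y` and nuclear norm no larger than the nuclear norm of `Y`.
#' @examples
#' singular_value_threshold(diag(c(3, 1, 0.2)), 0.5)
#' @export
singular_value_threshold <- function(Y, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("singular_value_threshold: 'lam' must be a positive scalar",
         call. = FALSE)
  Y <- as.matrix(Y)
  if (!all(is.finite(Y)))
    stop("singular_value_threshold: non-finite entries in 'Y'", call. = FALSE)
  s <- svd(Y)
  d <- pmax(s$d - lam, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim(Y)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Column-wise l2,1 shrinkage operator
#'
#' Proximal operator of the l2,1 norm (sum of column Euclidean norms). Each
#' column is scaled by `(norm - tau) / norm` when its norm strictly exceeds
#' `tau`, and zeroed otherwise; column directions are preserved.
#'
#' @param Q A numeric matrix.
#' @param tau Threshold, a positive scalar.
#' @return A matrix of the same shape as `Q`.
#' @examples
#' column_l21_shrink(matrix(c(3, 4), 2, 1), 1)  # scaled by 4/5
#' @export
column_l21_shrink <- function(Q, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("column_l21_shrink: 'tau' must be a positive scalar", call. = FALSE)
  Q <- as.matrix(Q)
  nrm <- sqrt(colSums(Q^2))
  scale <- ifelse(nrm > tau, (nrm - tau) / nrm, 0)
  scale[!is.finite(scale)] <- 0
  Q * rep(scale, each = nrow(Q))
}

# Frobenius norm helper used throughout the solver.
#' @noRd
fnorm <- function(x) sqrt(sum(x^2))

# Nuclear norm (sum of singular values).
#' @noRd
nuclear_norm <- function(x) sum(svd(x, nu = 0, nv = 0)$d)

# l2,1 norm: sum over columns of column Euclidean norms.
#' @noRd
l21_norm <- function(x) sum(sqrt(colSums(as.matrix(x)^2)))
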