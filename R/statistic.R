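check_gram_pair <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B)) stop("A and B must be matrices")
  n <- nrow(A)
  if (ncol(A) != n || nrow(B) != n || ncol(B) != n)
    stop("A and B must be square matrices of the same size")
  if (n < 4L) stop("the quadruple U-statistic needs n >= 4 subjects")
  tolA <- 1e-8 * max(1, max(abs(A)))
  tolB <- 1e-8 * max(1, max(abs(B)))
  if (max(abs(A - t(A))) > tolA || max(abs(B - t(B))) > tolB)
    stop("A and B must be symmetric (Gram) matrices")
  n
}

#' Quadruple-average dependence statistic, exact O(n^2) form
#'
#' The statistic averages, over all unordered quadruples of subjects, the
#' symmetrized kernel built from products of predictor and residual
#' inner-product contrasts:
#' phi(i1,i2,i3,i4) = (1/4) (A[i1,i3] - A[i1,i4] - A[i2,i3] + A[i2,i4]) *
#' (B[i1,i3] - B[i1,i4] - B[i2,i3] + B[i2,i4]), symmetrized over the three
#' pairings of the quadruple.  Its expectation is the squared norm of the
#' covariance-transformed deviation of the regression operator from the
#' hypothesized one, so it is zero exactly under the null.
#'
#' Rather than enumerating the ~n^4/24 quadruples, the sum over ordered
#' distinct quadruples of phi reduces exactly to
#' \deqn{(n-2)(n-3) S_2 - 2 (n-3) S_3 + S_4}
#' with \eqn{S_2 = \sum_{i \ne j} A_{ij} B_{ij}},
#' \eqn{S_3 = \sum_{i \ne j \ne k} A_{ij} B_{ik}} and
#' \eqn{S_4 = \sum A_{i_1 i_2} B_{i_3 i_4}} over four distinct indices,
#' each of which collapses to elementwise products, row sums and total
#' sums of the off-diagonal parts of A and B.  The reduction is certified
#' against \code{\link{flute_statistic_naive}} in the test suite.
#'
#' @param A n x n symmetric Gram matrix of predictor inner products.
#' @param B n x n symmetric Gram matrix of residual inner products.
#' @return The statistic (a scalar).
#' @seealso \code{\link{flute_statistic_naive}}, \code{\link{flute_test}}
#' @export
flute_statistic <- function(A, B) {
  n <- check_gram_pair(A, B)
  Ao <- A; diag(Ao) <- 0
  Bo <- B; diag(Bo) <- 0
  S2 <- sum(Ao * Bo)
  S3 <- sum(rowSums(Ao) * rowSums(Bo)) - S2
  S4 <- sum(Ao) * sum(Bo) - 2 * S2 - 4 * S3
  ((n - 2) * (n - 3) * S2 - 2 * (n - 3) * S3 + S4) /
    (n * (n - 1) * (n - 2) * (n - 3))
}

#' Quadruple-average statistic by literal enumeration
#'
#' Definition-of-record oracle: loops over all unordered quadruples and
#' the three pairings of each.  O(n^4); intended for n up to about 30.
#'
#' @inheritParams flute_statistic
#' @return The statistic (a scalar), identical to
#'   \code{\link{flute_statistic}} up to rounding.
#' @export
flute_statistic_naive <- function(A, B) {
  n <- check_gram_pair(A, B)
  phi <- function(i1, i2, i3, i4)
    0.25 * (A[i1, i3] - A[i1, i4] - A[i2, i3] + A[i2, i4]) *
           (B[i1, i3] - B[i1, i4] - B[i2, i3] + B[i2, i4])
  quads <- utils::combn(n, 4L)
  total <- 0
  for (c in seq_len(ncol(quads))) {
    q <- quads[, c]
    psi <- (phi(q[1L], q[2L], q[3L], q[4L]) +
            phi(q[1L], q[3L], q[2L], q[4L]) +
            phi(q[1L], q[4L], q[2L], q[3L])) / 3
    total <- total + psi
  }
  total / choose(n, 4L)
}

#' Unbiased estimator of the trace of a squared covariance operator
#'
#' Plug-in estimator built from pairwise inner products over distinct
#' index tuples,
#' \deqn{\widehat{tr}(\Sigma^2) = R_{1n} - 2 R_{2n} + R_{3n},}
#' where \eqn{R_{1n}} averages squared inner products over ordered
#' distinct pairs, \eqn{R_{2n}} averages products of chained inner
#' products over ordered distinct triples and \eqn{R_{3n}} over ordered
#' distinct quadruples, each normalized by the falling factorial
#' n!/(n-m)!.  The correction terms make the estimator exactly invariant
#' to adding a common shift to every subject; it is unbiased and ratio
#' consistent under the null and local alternatives.
#'
#' The tuple sums are evaluated with the same off-diagonal matrix
#' identities as \code{\link{flute_statistic}} (no tuple loops) and the
#' implementation is certified against \code{\link{tr_sq_estimate_naive}}
#' in the test suite.  The raw value can be negative in small samples;
#' callers that use it inside a variance should clip at zero (see
#' \code{\link{flute_test}}).
#'
#' @param G n x n symmetric Gram matrix of (typically centered)
#'   coefficient rows.
#' @return The trace estimate (a scalar, possibly negative at small n).
#' @export
tr_sq_estimate <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) stop("G must be square")
  n <- nrow(G)
  if (n < 4L) stop("the trace estimator needs n >= 4 subjects")
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("G must be symmetric")
  Go <- G; diag(Go) <- 0
  S2 <- sum(Go^2)
  S3 <- sum(rowSums(Go)^2) - S2
  S4 <- sum(Go)^2 - 2 * S2 - 4 * S3
  S2 / (n * (n - 1)) -
    2 * S3 / (n * (n - 1) * (n - 2)) +
    S4 / (n * (n - 1) * (n - 2) * (n - 3))
}

#' Trace estimator by literal tuple enumeration
#'
#' Oracle version of \code{\link{tr_sq_estimate}} looping over all
#' ordered distinct pairs, triples and quadruples.  O(n^4); intended for
#' n up to about 10.
#'
#' @inheritParams tr_sq_estimate
#' @export
tr_sq_estimate_naive <- function(G) {
  n <- nrow(G)
  if (n < 4L) stop("the trace estimator needs n >= 4 subjects")
  r1 <- 0; r2 <- 0; r3 <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) r1 <- r1 + G[i, j]^2
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (i != j && j != k && i != k) r2 <- r2 + G[i, j] * G[j, k]
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n)
    if (i != j && i != k && i != l && j != k && j != l && k != l)
      r3 <- r3 + G[i, j] * G[k, l]
  r1 / (n * (n - 1)) -
    2 * r2 / (n * (n - 1) * (n - 2)) +
    r3 / (n * (n - 1) * (n - 2) * (n - 3))
}

#' Residual loadings under a hypothesized regression surface
#'
#' Computes R_i = y_i - B0 xi_i in coefficient space, so that inner
#' products of residual differences equal the corresponding integrals of
#' paired residual contrasts.
#'
#' @param Y \code{coef_set} (or n x L matrix) of response loadings.
#' @param X \code{coef_set} (or n x K matrix) of predictor loadings.
#' @param beta0 L x K coefficient matrix of the hypothesized surface, or
#'   \code{NULL} for the zero surface (no-dependence null).
#' @return An n x L matrix of residual loadings (a \code{coef_set} when
#'   \code{Y} is one).
#' @export
residual_coeffs <- function(Y, X, beta0 = NULL) {
  y <- coef_matrix(Y)
  x <- coef_matrix(X)
  if (nrow(y) != nrow(x)) stop("X and Y must have the same number of rows")
  if (is.null(beta0)) {
    res <- y
  } else {
    beta0 <- as.matrix(beta0)
    if (nrow(beta0) != ncol(y) || ncol(beta0) != ncol(x))
      stop(sprintf("beta0 must be %d x %d, got %d x %d",
                   ncol(y), ncol(x), nrow(beta0), ncol(beta0)))
    res <- y - x %*% t(beta0)
  }
  if (inherits(Y, "coef_set")) coefficient_set(res, Y$basis) else res
}
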