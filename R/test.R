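flute_result <- function(...) {
  structure(list(...), class = "flute_result")
}

#' @export
print.flute_result <- function(x, ...) {
  cat(sprintf("\n\t%s\n\n", x$method))
  cat(sprintf("n = %d, K = %d, L = %s\n", x$n, x$K,
              if (is.null(x$L)) "1 (scalar)" else as.character(x$L)))
  cat(sprintf("statistic T = %.6g   n*T = %.6g\n", x$statistic, x$n_statistic))
  cat(sprintf("tr(Sigma^2)^ = %.6g   %s = %.6g\n",
              x$tr_sigma2_hat,
              if (is.null(x$L)) "sigma2^" else "tr(Lambda^2)^",
              if (is.null(x$L)) x$sigma2_hat else x$tr_lambda2_hat))
  cat(sprintf("z = %.4f,  one-sided p-value = %.4g\n", x$z, x$p_value))
  cat(sprintf("alpha = %g: %s H0\n\n", x$alpha,
              if (x$reject) "reject" else "do not reject"))
  if (isTRUE(x$clipped))
    cat("note: a negative trace estimate was clipped to zero upstream\n")
  invisible(x)
}

center_rows <- function(m) sweep(m, 2L, colMeans(m), "-")

#' Dependence test for a functional response
#'
#' Tests whether the regression operator of a functional linear model with
#' functional response equals a hypothesized surface (default: zero, i.e.
#' the response does not depend on the predictor).  The statistic is the
#' quadruple-average U-statistic of \code{\link{flute_statistic}} applied
#' to the predictor Gram and the residual Gram; it is standardized by
#' plug-in trace estimates of the squared covariance operators of the
#' predictor and of the residual process, and compared with the upper
#' tail of the standard normal:
#' reject when n T >= sqrt(2 tr(Lambda^2)^ tr(Sigma^2)^) z_alpha.
#'
#' The statistic itself is invariant to adding a fixed curve to all
#' predictors and/or all responses.  The trace plug-ins are computed on
#' mean-centered coefficient rows (the estimator's tuple corrections make
#' it shift-invariant as well, so \code{center} only matters through
#' rounding); the residual trace uses the residuals under \code{beta0} in
#' the same estimator.
#'
#' @param X Predictor loadings: a \code{coef_set} or n x K matrix.
#' @param Y Response loadings: a \code{coef_set} or n x L matrix.
#' @param beta0 Hypothesized L x K surface coefficients, or \code{NULL}
#'   for the zero surface.
#' @param alpha Significance level in (0, 1).
#' @param center Center coefficient rows before the trace plug-ins.
#' @return A \code{flute_result} with the statistic, trace estimates,
#'   standardized z, one-sided p-value and decision.
#' @examples
#' set.seed(1)
#' d <- simulation_design(n = 40, K = 5, L = 5, betasq = 0.5)
#' dat <- gen_functional_data(d)
#' flute_test(dat$X, dat$Y)
#' @export
flute_test <- function(X, Y, beta0 = NULL, alpha = 0.05, center = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  xi <- coef_matrix(X)
  yl <- coef_matrix(Y)
  n <- nrow(xi)
  if (n < 4L) stop("the test needs n >= 4 subjects")
  res <- coef_matrix(residual_coeffs(yl, xi, beta0))
  Tn <- flute_statistic(tcrossprod(xi), tcrossprod(res))
  xc <- if (center) center_rows(xi) else xi
  rc <- if (center) center_rows(res) else res
  tr_sigma2 <- tr_sq_estimate(tcrossprod(xc))
  tr_lambda2 <- tr_sq_estimate(tcrossprod(rc))
  clipped <- tr_sigma2 < 0 || tr_lambda2 < 0
  tr_sigma2 <- max(tr_sigma2, 0)
  tr_lambda2 <- max(tr_lambda2, 0)
  denom <- sqrt(2 * tr_sigma2 * tr_lambda2)
  if (denom <= 0)
    stop("calibration error: nonpositive trace estimates, cannot standardize")
  z <- n * Tn / denom
  p <- stats::pnorm(z, lower.tail = FALSE)
  flute_result(
    method = "Functional-response dependence test (quadruple U-statistic)",
    statistic = Tn, n_statistic = n * Tn,
    tr_sigma2_hat = tr_sigma2, tr_lambda2_hat = tr_lambda2,
    z = z, p_value = p, alpha = alpha,
    reject = z >= stats::qnorm(1 - alpha),
    n = n, K = ncol(xi), L = ncol(res),
    clipped = clipped,
    decisions = list(centered_trace_plugins = center,
                     residual_trace = "plug-in on residuals under beta0",
                     sided = "one-sided upper"))
}

#' Asymptotic power of the dependence test
#'
#' Power against a local alternative with effect size
#' \eqn{\|C(\beta - \beta_0)\|^2}:
#' \deqn{\Upsilon = \Phi(-z_\alpha + r_n), \quad
#'   r_n = n \|C(\beta-\beta_0)\|^2 / \sqrt{2\, tr(\Lambda^2)\, tr(\Sigma^2)},}
#' the signal-to-noise ratio.  At zero effect the power equals alpha
#' exactly; it is monotone increasing in the effect and in n, and tends
#' to 1 when r_n diverges.
#'
#' @param effect Nonnegative effect size \eqn{\|C(\beta-\beta_0)\|^2}.
#' @param tr_lambda2,tr_sigma2 Positive traces of the squared residual and
#'   predictor covariance operators.
#' @param n Sample size.
#' @param alpha Significance level.
#' @return Power in [0, 1].
#' @export
asymptotic_power <- function(effect, tr_lambda2, tr_sigma2, n, alpha = 0.05) {
  if (any(effect < 0)) stop("effect must be nonnegative")
  if (tr_lambda2 <= 0 || tr_sigma2 <= 0) stop("traces must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  r_n <- n * effect / sqrt(2 * tr_lambda2 * tr_sigma2)
  stats::pnorm(-stats::qnorm(1 - alpha) + r_n)
}
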