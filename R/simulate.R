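#' Describe one cell of a Monte-Carlo size/power study
#'
#' Bundles the generative conditions for one simulation cell: sample
#' size, basis truncations, moving-average dependency range of the
#' predictor loadings, signal level, error covariance and response type.
#'
#' @param n Sample size.
#' @param K Predictor basis truncation.
#' @param L Response basis truncation (functional response; ignored for
#'   scalar).
#' @param t_ma Moving-average dependency range T of the predictor
#'   loadings (T = 1 gives iid standard-normal loadings).
#' @param betasq Signal level |beta|^2 >= 0; 0 is the null.
#' @param error_cov \code{"identity"} (unit-variance error loadings) or
#'   \code{"heteroscedastic_1_over_l"} (Var(eps_l) = 1/l).
#' @param response \code{"functional"} or \code{"scalar"}.
#' @param alpha_levels Nominal significance levels evaluated by study
#'   drivers.
#' @param reps Default Monte-Carlo replicate count for study drivers.
#' @param seed Optional master seed recorded with the design.
#' @param rho_policy \code{"per_replicate"} draws the MA weights rho anew
#'   for every simulated dataset (treats rho as part of the random
#'   design); \code{"fixed_per_cell"} draws them once per cell.
#' @param normalize_beta Rescale the signal surface so its squared L2
#'   norm equals \code{betasq} (sensitivity option; the default keeps the
#'   literal surface scale).
#' @return An object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(n, K, L = K, t_ma = 5, betasq = 0,
                              error_cov = c("identity",
                                            "heteroscedastic_1_over_l"),
                              response = c("functional", "scalar"),
                              alpha_levels = c(0.05, 0.1),
                              reps = 1000L, seed = NULL,
                              rho_policy = c("per_replicate",
                                             "fixed_per_cell"),
                              normalize_beta = FALSE) {
  error_cov <- match.arg(error_cov)
  response <- match.arg(response)
  rho_policy <- match.arg(rho_policy)
  stopifnot(n >= 4, K >= 1, L >= 1, t_ma >= 1, betasq >= 0, reps >= 1,
            all(alpha_levels > 0 & alpha_levels < 1))
  structure(list(n = as.integer(n), K = as.integer(K), L = as.integer(L),
                 T = as.integer(t_ma), betasq = betasq,
                 error_cov = error_cov, response = response,
                 alpha_levels = alpha_levels, reps = as.integer(reps),
                 seed = seed, rho_policy = rho_policy,
                 normalize_beta = isTRUE(normalize_beta)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0("<simulation_design> %s response: n=%d K=%d L=%d T=%d ",
                     "|beta|^2=%g errors=%s rho=%s reps=%d\n"),
              x$response, x$n, x$K, x$L, x$T, x$betasq, x$error_cov,
              x$rho_policy, x$reps))
  invisible(x)
}

#' Moving-average factor loadings
#'
#' Generates n iid loading rows xi_i of length K from the moving-average
#' factor model xi_ik = rho_1 N_ik + rho_2 N_i(k+1) + ... +
#' rho_T N_i(k+T-1), with N_i ~ N(0, I_(K+T-1)).  The implied loading
#' covariance is banded with bandwidth T - 1 (see \code{\link{ma_cov}}),
#' so T controls the range of dependence between loadings.
#'
#' @param n Number of rows.
#' @param K Number of loadings per row.
#' @param rho Length-T weight vector; if \code{NULL}, drawn from U(0, 1).
#' @param t_ma MA range T, used only when \code{rho} is \code{NULL}.
#' @return n x K matrix with attribute \code{"rho"}.
#' @export
ma_loadings <- function(n, K, rho = NULL, t_ma = length(rho)) {
  if (is.null(rho)) {
    if (is.null(t_ma) || length(t_ma) != 1L || t_ma < 1)
      stop("give either rho or a positive t_ma")
    rho <- stats::runif(t_ma)
  }
  t_ma <- length(rho)
  N <- matrix(stats::rnorm(n * (K + t_ma - 1L)), n, K + t_ma - 1L)
  xi <- matrix(0, n, K)
  for (t in seq_len(t_ma))
    xi <- xi + rho[t] * N[, t:(t + K - 1L), drop = FALSE]
  attr(xi, "rho") <- rho
  xi
}

#' Closed-form covariance of moving-average loadings
#'
#' The (k, l) entry is sum_t rho_t rho_(t+|k-l|) for |k - l| < T and zero
#' beyond: a symmetric positive semidefinite band matrix.
#'
#' @param K Dimension.
#' @param rho Length-T MA weight vector.
#' @return K x K covariance matrix.
#' @export
ma_cov <- function(K, rho) {
  t_ma <- length(rho)
  S <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    d <- abs(k - l)
    if (d < t_ma)
      S[k, l] <- sum(rho[seq_len(t_ma - d)] * rho[(1L + d):t_ma])
  }
  S
}

#' Basis coefficients of the benchmark signal surface
#'
#' The study's regression surface is beta(t, s) = |beta|^2
#' exp((t^2 + s^2)/2) on [0, 1]^2.  Its coefficient matrix on a pair of
#' orthonormal bases is computed by tensor-product trapezoid quadrature;
#' because the surface is separable the matrix is exactly rank one,
#' beta_lk = |beta|^2 a_l a_k with a_m the quadrature loading of
#' exp(u^2/2) on basis function m.
#'
#' The printed scale is kept literally by default: the squared L2 norm of
#' the surface is then |beta|^4 times the norm of the exponential kernel,
#' not |beta|^2.  \code{normalize = TRUE} rescales so the squared L2 norm
#' equals \code{betasq} (sensitivity analysis).
#'
#' @param betasq Signal level |beta|^2 >= 0.
#' @param resp_basis,pred_basis \code{basis_spec}s for the response (L)
#'   and predictor (K) directions.
#' @param normalize Rescale to squared L2 norm \code{betasq}.
#' @param ngrid Quadrature points per axis (>= 401).
#' @return L x K coefficient matrix.
#' @export
beta_surface_coeffs <- function(betasq, resp_basis, pred_basis,
                                normalize = FALSE, ngrid = 401L) {
  stopifnot(inherits(resp_basis, "basis_spec"),
            inherits(pred_basis, "basis_spec"), betasq >= 0, ngrid >= 401L)
  if (betasq == 0)
    return(matrix(0, resp_basis$size, pred_basis$size))
  g <- seq(0, 1, length.out = ngrid)
  w <- trap_weights(g)
  kern <- exp(g^2 / 2)
  a_resp <- colSums(w * kern * evaluate_basis(resp_basis, g))
  a_pred <- colSums(w * kern * evaluate_basis(pred_basis, g))
  B <- betasq * outer(a_resp, a_pred)
  if (normalize) {
    norm2 <- sum(w * kern^2)^2 * betasq^2   # squared L2 norm of the surface
    B <- B * sqrt(betasq / norm2)
  }
  B
}

#' Uniform coefficient vector for the scalar-response signal
#'
#' beta_k = sqrt(betasq / K) for every k, so that the squared loading sum
#' equals betasq exactly.
#'
#' @param betasq Signal level |beta|^2 >= 0.
#' @param K Number of loadings.
#' @return Length-K numeric vector.
#' @export
beta_vector_coeffs <- function(betasq, K) {
  stopifnot(betasq >= 0, K >= 1)
  rep(sqrt(betasq / K), K)
}

error_sd <- function(design) {
  switch(design$error_cov,
         identity = rep(1, design$L),
         heteroscedastic_1_over_l = 1 / sqrt(seq_len(design$L)))
}

#' Generate one functional-response dataset
#'
#' Draws predictor loadings from the moving-average factor model, builds
#' the response loadings as y_i = B xi_i + eps_i with B the surface
#' coefficient matrix of \code{\link{beta_surface_coeffs}} and Gaussian
#' error loadings with identity or 1/l variances.  Data are generated
#' directly in coefficient space, which is exact under an orthonormal
#' basis; use \code{\link{render_curves}} to obtain grid-sampled curves.
#'
#' @param design A \code{simulation_design} with
#'   \code{response = "functional"}.
#' @param rho Optional fixed MA weights (overrides the design's
#'   rho policy for this draw).
#' @param seed Optional seed set before drawing.
#' @return List with \code{X}, \code{Y} (\code{coef_set}s on Fourier
#'   bases), \code{beta} (true surface coefficients) and \code{rho}.
#' @export
gen_functional_data <- function(design, rho = NULL, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            design$response == "functional")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho)) rho <- stats::runif(design$T)
  xi <- ma_loadings(design$n, design$K, rho = rho)
  pred_basis <- basis_spec("fourier", design$K)
  resp_basis <- basis_spec("fourier", design$L)
  B <- beta_surface_coeffs(design$betasq, resp_basis, pred_basis,
                           normalize = design$normalize_beta)
  eps <- matrix(stats::rnorm(design$n * design$L), design$n, design$L)
  eps <- sweep(eps, 2L, error_sd(design), "*")
  y <- xi %*% t(B) + eps
  list(X = coefficient_set(xi, pred_basis),
       Y = coefficient_set(y, resp_basis),
       beta = B, rho = rho)
}

#' Generate one scalar-response dataset
#'
#' y_i = <xi_i, beta> + eps_i with beta_k = sqrt(betasq / K) and
#' eps_i ~ N(0, 1); predictor loadings as in
#' \code{\link{gen_functional_data}}.
#'
#' @inheritParams gen_functional_data
#' @return List with \code{X} (\code{coef_set}), \code{y} (numeric
#'   vector), \code{beta} (length-K vector) and \code{rho}.
#' @export
gen_scalar_data <- function(design, rho = NULL, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            design$response == "scalar")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho)) rho <- stats::runif(design$T)
  xi <- ma_loadings(design$n, design$K, rho = rho)
  beta <- beta_vector_coeffs(design$betasq, design$K)
  y <- as.vector(xi %*% beta) + stats::rnorm(design$n)
  list(X = coefficient_set(xi, basis_spec("fourier", design$K)),
       y = y, beta = beta, rho = rho)
}
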