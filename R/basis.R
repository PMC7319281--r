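#' Orthonormal basis specification on [0, 1]
#'
#' Defines a family of basis functions of the Hilbert space L^2[0, 1]
#' together with a truncation size.  The Fourier family is orthonormal in
#' closed form (constant, then sine/cosine pairs scaled by sqrt(2)); the
#' B-spline family is orthonormalized numerically against the trapezoid
#' inner product on a fine reference grid, so that in both cases the L2
#' inner product of two curves equals the Euclidean dot product of their
#' coefficient vectors.
#'
#' @param family Basis family, one of \code{"fourier"} or \code{"bspline"}.
#' @param size Number of basis functions (a positive integer).
#' @return An object of class \code{"basis_spec"}.
#' @examples
#' bs <- basis_spec("fourier", 5)
#' Phi <- evaluate_basis(bs, seq(0, 1, length.out = 201))
#' @export
basis_spec <- function(family = c("fourier", "bspline"), size) {
  family <- match.arg(family)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L)
    stop("'size' must be a positive integer")
  structure(list(family = family, size = size, domain = c(0, 1)),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> family=%s size=%d domain=[0,1]\n",
              x$family, x$size))
  invisible(x)
}

# trapezoid quadrature weights for an increasing grid
trap_weights <- function(grid) {
  g <- length(grid)
  if (g < 2L) stop("quadrature grid needs at least 2 points")
  w <- numeric(g)
  w[1L] <- (grid[2L] - grid[1L]) / 2
  w[g] <- (grid[g] - grid[g - 1L]) / 2
  if (g > 2L) w[2:(g - 1L)] <- (grid[3:g] - grid[1:(g - 2L)]) / 2
  w
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || anyNA(grid))
    stop("grid must be numeric without missing values")
  if (any(grid < 0 | grid > 1))
    stop("grid points must lie in [0, 1]; rescale the raw support first")
  grid
}

fourier_matrix <- function(grid, size) {
  out <- matrix(0, length(grid), size)
  out[, 1L] <- 1
  if (size > 1L) for (k in 2:size) {
    h <- k %/% 2L
    out[, k] <- if (k %% 2L == 0L) sqrt(2) * sin(2 * pi * h * grid)
                else sqrt(2) * cos(2 * pi * h * grid)
  }
  out
}

# B-spline columns orthonormalized (QR against trapezoid weights) on a
# fixed 2001-point reference grid, then interpolated to the target grid.
bspline_matrix <- function(grid, size) {
  if (size < 4L)
    stop("bspline family needs size >= 4 (cubic splines)")
  ref <- seq(0, 1, length.out = 2001L)
  nknots <- size - 2L  # interior + boundary knots for cubic B-splines
  knots <- seq(0, 1, length.out = nknots)
  aug <- c(rep(0, 3), knots, rep(1, 3))
  raw <- splines::splineDesign(aug, ref, ord = 4L)
  w <- trap_weights(ref)
  qr_ <- qr(sqrt(w) * raw)
  Qn <- qr.Q(qr_) / sqrt(w)          # orthonormal in the L2(trapezoid) sense
  # fix signs so the first nonzero weighted loading is positive
  sgn <- apply(Qn, 2L, function(col) sign(col[which.max(abs(col))]))
  Qn <- sweep(Qn, 2L, sgn, "*")
  apply(Qn, 2L, function(col) stats::approx(ref, col, xout = grid)$y)
}

#' Evaluate a basis on a grid
#'
#' Column k of the returned matrix holds basis function k evaluated at the
#' grid points.  The Fourier ordering is 1, sqrt(2) sin(2 pi s),
#' sqrt(2) cos(2 pi s), sqrt(2) sin(4 pi s), sqrt(2) cos(4 pi s), ...
#'
#' @param basis A \code{basis_spec}.
#' @param grid Numeric vector of evaluation points in [0, 1].
#' @return A \code{length(grid) x basis$size} matrix.
#' @export
evaluate_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "basis_spec"))
  grid <- check_grid(grid)
  switch(basis$family,
         fourier = fourier_matrix(grid, basis$size),
         bspline = {
           mat <- bspline_matrix(grid, basis$size)
           if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(grid))
           mat
         })
}

#' A sample of curves observed on a common grid
#'
#' @param values n x G numeric matrix; row i is subject i's curve sampled at
#'   the grid points.
#' @param grid Strictly increasing vector of G points in [0, 1].
#' @return An object of class \code{"curve_set"}.
#' @export
curve_set <- function(values, grid) {
  values <- as.matrix(values)
  grid <- check_grid(as.numeric(grid))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (ncol(values) != length(grid))
    stop("ncol(values) must equal length(grid)")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> n=%d curves on %d grid points in [%.3g, %.3g]\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Basis-coefficient representation of a sample of curves
#'
#' Row i holds the loadings of subject i on the (orthonormal) basis, so
#' L2 inner products between curves reduce to Euclidean dot products
#' between rows.
#'
#' @param coeffs n x K numeric matrix of loadings.
#' @param basis The \code{basis_spec} the loadings refer to.
#' @return An object of class \code{"coef_set"}.
#' @export
coefficient_set <- function(coeffs, basis) {
  stopifnot(inherits(basis, "basis_spec"))
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  if (ncol(coeffs) != basis$size)
    stop("ncol(coeffs) must equal basis$size")
  structure(list(coeffs = coeffs, basis = basis), class = "coef_set")
}

#' @export
print.coef_set <- function(x, ...) {
  cat(sprintf("<coef_set> n=%d loadings on %s basis of size %d\n",
              nrow(x$coeffs), x$basis$family, x$basis$size))
  invisible(x)
}

coef_matrix <- function(x) {
  if (inherits(x, "coef_set")) x$coeffs
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, ncol = 1L)
  else stop("expected a coef_set or a numeric matrix")
}

#' Project curves onto a basis by least squares
#'
#' Each curve is regressed on the basis functions evaluated at the
#' observation grid; the fitted coefficients minimize the discrete
#' least-squares reconstruction error.  For curves lying in the span of
#' the basis the projection is exact.
#'
#' @param curves A \code{curve_set}.
#' @param basis A \code{basis_spec} with \code{size <=} number of grid
#'   points.
#' @return A \code{coef_set} with one coefficient row per curve.
#' @export
project_curves <- function(curves, basis) {
  stopifnot(inherits(curves, "curve_set"), inherits(basis, "basis_spec"))
  G <- length(curves$grid)
  if (G < 2L) stop("grid must have at least 2 points")
  if (G < basis$size)
    stop(sprintf("grid has %d points but basis size is %d: rank-deficient fit",
                 G, basis$size))
  Phi <- evaluate_basis(basis, curves$grid)
  qr_ <- qr(Phi)
  if (qr_$rank < basis$size)
    stop("design matrix is rank deficient on this grid")
  coeffs <- t(qr.coef(qr_, t(curves$values)))
  coefficient_set(coeffs, basis)
}

#' Render coefficient rows back into curves on a grid
#'
#' @param coeffs A \code{coef_set}.
#' @param grid Evaluation grid in [0, 1].
#' @return A \code{curve_set}.
#' @export
render_curves <- function(coeffs, grid) {
  stopifnot(inherits(coeffs, "coef_set"))
  Phi <- evaluate_basis(coeffs$basis, grid)
  curve_set(coeffs$coeffs %*% t(Phi), grid)
}

#' Pairwise L2 inner products of curve samples
#'
#' Under an orthonormal basis the inner product of two curves equals the
#' dot product of their coefficient rows, so the Gram matrix is just
#' \code{tcrossprod} of the coefficient matrices.
#'
#' @param A A \code{coef_set} (or plain coefficient matrix).
#' @param B Optional second \code{coef_set} on the same basis; if missing,
#'   the symmetric Gram of \code{A} with itself is returned.
#' @return An n_A x n_B matrix of inner products.
#' @export
gram_matrix <- function(A, B = NULL) {
  a <- coef_matrix(A)
  if (is.null(B)) return(tcrossprod(a))
  b <- coef_matrix(B)
  if (inherits(A, "coef_set") && inherits(B, "coef_set")) {
    if (!identical(A$basis$family, B$basis$family) ||
        A$basis$size != B$basis$size)
      stop("A and B must share the same basis")
  }
  if (ncol(a) != ncol(b)) stop("A and B must share the same basis size")
  tcrossprod(a, b)
}
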