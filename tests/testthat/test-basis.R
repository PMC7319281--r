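test_that("fourier basis has the documented closed forms", {
  grid <- seq(0, 1, length.out = 11)
  b1 <- evaluate_basis(basis_spec("fourier", 1), grid)
  expect_equal(b1, matrix(1, 11, 1))

  row <- evaluate_basis(basis_spec("fourier", 3), 0.25)
  expect_equal(as.vector(row), c(1, sqrt(2) * sin(pi / 2), sqrt(2) * cos(pi / 2)),
               tolerance = 1e-12)

  expect_error(evaluate_basis(basis_spec("fourier", 3), c(0.2, 1.1)),
               "\\[0, 1\\]")
})

test_that("fourier Gram is the identity under quadrature for K up to 25", {
  grid <- seq(0, 1, length.out = 2001)
  for (K in c(5, 11, 25)) {
    Phi <- evaluate_basis(basis_spec("fourier", K), grid)
    G <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in i:K)
      G[i, j] <- G[j, i] <- quad_inner(Phi[, i], Phi[, j], grid)
    expect_lt(max(abs(G - diag(K))), 1e-6)
  }
})

test_that("orthonormalized bspline family also has identity Gram", {
  grid <- seq(0, 1, length.out = 2001)
  Phi <- evaluate_basis(basis_spec("bspline", 7), grid)
  G <- crossprod(Phi * sqrt(flute:::trap_weights(grid)))
  expect_lt(max(abs(G - diag(7))), 1e-6)
})

test_that("projection recovers coefficients of curves in the basis span", {
  set.seed(101)
  basis <- basis_spec("fourier", 11)
  grid <- seq(0, 1, length.out = 365)
  cmat <- matrix(rnorm(6 * 11), 6)
  curves <- render_curves(coefficient_set(cmat, basis), grid)
  proj <- project_curves(curves, basis)
  expect_equal(proj$coeffs, cmat, tolerance = 1e-8)

  zero <- curve_set(matrix(0, 3, 365), grid)
  expect_equal(project_curves(zero, basis)$coeffs, matrix(0, 3, 11))
})

test_that("projection agrees with independent normal-equations solve and is idempotent", {
  set.seed(102)
  basis <- basis_spec("fourier", 11)
  grid <- seq(0, 1, length.out = 365)
  # smooth curves NOT in the basis span
  vals <- t(sapply(1:5, function(i) sin(3 * grid + i) + grid^2 * i))
  curves <- curve_set(vals, grid)
  proj <- project_curves(curves, basis)
  Phi <- evaluate_basis(basis, grid)
  expect_equal(proj$coeffs, normal_eq_coeffs(vals, Phi), tolerance = 1e-8)
  # fitted curves project back to the same coefficients (fixed point)
  refit <- project_curves(render_curves(proj, grid), basis)
  expect_equal(refit$coeffs, proj$coeffs, tolerance = 1e-8)
})

test_that("rank-deficient designs are refused", {
  basis <- basis_spec("fourier", 11)
  expect_error(project_curves(curve_set(matrix(1, 2, 5),
                                        seq(0, 1, length.out = 5)), basis),
               "rank")
})

test_that("gram matrix matches dense-grid quadrature of curve products", {
  set.seed(103)
  basis <- basis_spec("fourier", 5)
  grid <- seq(0, 1, length.out = 2001)
  cmat <- matrix(rnorm(4 * 5), 4)
  G <- gram_matrix(coefficient_set(cmat, basis))
  vals <- render_curves(coefficient_set(cmat, basis), grid)$values
  for (i in 1:4) for (j in 1:4)
    expect_equal(G[i, j], quad_inner(vals[i, ], vals[j, ], grid),
                 tolerance = 1e-5)
})

test_that("gram matrix is bilinear and rotation invariant", {
  set.seed(104)
  basis <- basis_spec("fourier", 6)
  cmat <- matrix(rnorm(5 * 6), 5)
  A <- coefficient_set(cmat, basis)
  expect_equal(gram_matrix(coefficient_set(2 * cmat, basis)),
               4 * gram_matrix(A))
  expect_equal(gram_matrix(coefficient_set(diag(6), basis)), diag(6))
  # simultaneous orthonormal rotation of the coefficient space
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(gram_matrix(coefficient_set(cmat %*% Q, basis)),
               gram_matrix(A), tolerance = 1e-10)
  # basis mismatch is a contract error
  B5 <- coefficient_set(matrix(rnorm(10), 2), basis_spec("fourier", 5))
  expect_error(gram_matrix(A, B5), "basis")
})
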