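test_that("degenerate MA range gives iid standard normal loadings", {
  set.seed(601)
  xi <- ma_loadings(5000, 4, rho = 1)
  S <- cov(xi)
  expect_lt(max(abs(S - diag(4))), 3 * sqrt(2 / 5000) + 0.03)
  expect_lt(max(abs(colMeans(xi))), 3 / sqrt(5000) + 0.02)
})

test_that("MA loadings match the closed-form banded covariance", {
  set.seed(602)
  rho <- c(0.7, 0.4)
  xi <- ma_loadings(20000, 5, rho = rho)
  S_hat <- cov(xi)
  S <- ma_cov(5, rho)
  # lag-1 covariance is rho1*rho2; entries within ~3 MC SEs
  expect_equal(S[1, 2], 0.7 * 0.4)
  se <- 3 * sqrt(2) * max(diag(S)) / sqrt(20000)
  expect_lt(max(abs(S_hat - S)), se + 0.02)
  # lags at or beyond T are exactly zero in the model, near zero in data
  expect_true(all(S[abs(row(S) - col(S)) >= 2] == 0))
  expect_lt(max(abs(S_hat[abs(row(S_hat) - col(S_hat)) >= 2])), 0.03)
})

test_that("MA covariance is symmetric positive semidefinite and banded", {
  set.seed(603)
  for (t_ma in c(1, 3, 5)) {
    rho <- runif(t_ma)
    S <- ma_cov(7, rho)
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    expect_true(all(S[abs(row(S) - col(S)) >= t_ma] == 0))
  }
})

test_that("signal surface coefficients are rank one and linear in the level", {
  pb <- basis_spec("fourier", 5)
  rb <- basis_spec("fourier", 4)
  expect_equal(beta_surface_coeffs(0, rb, pb), matrix(0, 4, 5))
  B1 <- beta_surface_coeffs(0.1, rb, pb)
  expect_equal(dim(B1), c(4L, 5L))
  expect_lt(svd(B1)$d[2], 1e-8 * svd(B1)$d[1])  # separable => rank 1
  expect_equal(beta_surface_coeffs(0.2, rb, pb), 2 * B1, tolerance = 1e-12)
})

test_that("surface coefficients match independent 2-D quadrature", {
  pb <- basis_spec("fourier", 3)
  rb <- basis_spec("fourier", 3)
  B <- beta_surface_coeffs(0.3, rb, pb)
  g <- seq(0, 1, length.out = 801)
  Phi <- evaluate_basis(pb, g)
  for (l in 1:3) for (k in 1:3) {
    inner_t <- vapply(seq_along(g), function(ti)
      quad_inner(0.3 * exp((g[ti]^2 + g^2) / 2), Phi[, k], g), 0)
    expect_equal(B[l, k], quad_inner(inner_t, Phi[, l], g), tolerance = 1e-4)
  }
})

test_that("normalized surfaces have squared L2 norm equal to the level", {
  pb <- basis_spec("fourier", 11)
  B <- beta_surface_coeffs(0.1, pb, pb, normalize = TRUE)
  # the basis captures nearly all of the smooth surface's norm
  expect_equal(sum(B^2), 0.1, tolerance = 0.01)
})

test_that("scalar signal loadings square-sum to the level exactly", {
  for (b2 in c(0, 0.04, 0.5)) {
    beta <- beta_vector_coeffs(b2, 7)
    expect_equal(sum(beta^2), b2, tolerance = 1e-14)
  }
})

test_that("functional generator respects the design covariances", {
  set.seed(604)
  d <- simulation_design(n = 4000, K = 4, L = 6, betasq = 0,
                         error_cov = "heteroscedastic_1_over_l")
  dat <- gen_functional_data(d)
  v <- apply(dat$Y$coeffs, 2, var)   # null: Y = eps
  expect_lt(max(abs(v - 1 / (1:6)) * sqrt(4000 / 2) / (1 / (1:6))), 4)
  # noiseless check: response built from the surface alone has zero residual
  xi <- dat$X$coeffs
  y_clean <- xi %*% t(beta_surface_coeffs(0.2, basis_spec("fourier", 6),
                                          basis_spec("fourier", 4)))
  expect_equal(residual_coeffs(y_clean, xi,
                               beta_surface_coeffs(0.2,
                                                   basis_spec("fourier", 6),
                                                   basis_spec("fourier", 4))),
               matrix(0, 4000, 6), tolerance = 1e-10)
})

test_that("generators are reproducible from a seed", {
  d <- simulation_design(n = 20, K = 5, L = 5, betasq = 0.1)
  a <- gen_functional_data(d, seed = 99)
  b <- gen_functional_data(d, seed = 99)
  expect_identical(a$X$coeffs, b$X$coeffs)
  expect_identical(a$Y$coeffs, b$Y$coeffs)
  expect_identical(a$rho, b$rho)
  ds <- simulation_design(n = 20, K = 5, betasq = 0.1, response = "scalar")
  expect_identical(gen_scalar_data(ds, seed = 7)$y,
                   gen_scalar_data(ds, seed = 7)$y)
})
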