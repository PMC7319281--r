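test_that("closed-form statistic equals quadruple enumeration on random instances", {
  set.seed(301)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    g <- random_gram_pair(n)
    fast <- flute_statistic(g$A, g$B)
    slow <- flute_statistic_naive(g$A, g$B)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("zero residuals give a zero statistic", {
  set.seed(302)
  A <- random_gram_pair(8)$A
  expect_equal(flute_statistic(A, matrix(0, 8, 8)), 0)
})

test_that("statistic is invariant to location shifts of either sample", {
  set.seed(303)
  n <- 15
  X <- matrix(rnorm(n * 4), n)
  Y <- matrix(rnorm(n * 3), n)
  t0 <- flute_statistic(tcrossprod(X), tcrossprod(Y))
  shift_x <- matrix(rnorm(4), n, 4, byrow = TRUE)
  shift_y <- matrix(rnorm(3), n, 3, byrow = TRUE)
  t1 <- flute_statistic(tcrossprod(X + shift_x), tcrossprod(Y + shift_y))
  expect_equal(t1, t0, tolerance = 1e-10)
})

test_that("statistic scales exactly as c^2 under residual scaling", {
  set.seed(304)
  n <- 12
  X <- matrix(rnorm(n * 4), n)
  Y <- matrix(rnorm(n * 3), n)
  t0 <- flute_statistic(tcrossprod(X), tcrossprod(Y))
  t3 <- flute_statistic(tcrossprod(X), tcrossprod(3 * Y))
  expect_equal(t3, 9 * t0, tolerance = 1e-12)
})

test_that("statistic is invariant under relabeling of subjects", {
  set.seed(305)
  g <- random_gram_pair(9)
  perm <- sample(9)
  expect_equal(flute_statistic(g$A[perm, perm], g$B[perm, perm]),
               flute_statistic(g$A, g$B), tolerance = 1e-12)
})

test_that("contract violations are rejected", {
  g <- random_gram_pair(8)
  expect_error(flute_statistic(g$A[1:3, 1:3], g$B[1:3, 1:3]), "n >= 4")
  Abad <- g$A; Abad[1, 2] <- Abad[1, 2] + 1
  expect_error(flute_statistic(Abad, g$B), "symmetric")
})

test_that("the statistic is mean-zero under independence", {
  set.seed(306)
  tn <- replicate(400, {
    X <- matrix(rnorm(10 * 3), 10)
    Y <- matrix(rnorm(10 * 3), 10)
    flute_statistic(tcrossprod(X), tcrossprod(Y))
  })
  # E[T] = 0 under the null; 4 MC SEs around zero
  expect_lt(abs(mean(tn)), 4 * stats::sd(tn) / sqrt(length(tn)))
})

test_that("residual inner products match dense-grid quadrature of paired contrasts", {
  set.seed(307)
  n <- 5; K <- 4; L <- 3
  pb <- basis_spec("fourier", K); rb <- basis_spec("fourier", L)
  X <- coefficient_set(matrix(rnorm(n * K), n), pb)
  Y <- coefficient_set(matrix(rnorm(n * L), n), rb)
  beta0 <- matrix(rnorm(L * K), L, K)
  R <- residual_coeffs(Y, X, beta0)
  grid <- seq(0, 1, length.out = 2001)
  xv <- render_curves(X, grid)$values
  yv <- render_curves(Y, grid)$values
  Phi_r <- evaluate_basis(rb, grid)
  b0_curve <- function(xi_row) as.vector(Phi_r %*% (beta0 %*% xi_row))
  pi_curve <- function(i, j)
    yv[i, ] - yv[j, ] - (b0_curve(X$coeffs[i, ]) - b0_curve(X$coeffs[j, ]))
  for (pair in list(c(1, 2, 3, 4), c(2, 5, 1, 3))) {
    lhs <- sum((R$coeffs[pair[1], ] - R$coeffs[pair[2], ]) *
               (R$coeffs[pair[3], ] - R$coeffs[pair[4], ]))
    rhs <- quad_inner(pi_curve(pair[1], pair[2]),
                      pi_curve(pair[3], pair[4]), grid)
    expect_equal(lhs, rhs, tolerance = 1e-5)
  }
})

test_that("residuals reduce correctly in the exact and null cases", {
  set.seed(308)
  n <- 6; K <- 4; L <- 3
  X <- matrix(rnorm(n * K), n)
  beta0 <- matrix(rnorm(L * K), L, K)
  expect_equal(residual_coeffs(X %*% t(beta0), X, beta0),
               matrix(0, n, L), tolerance = 1e-12)
  Y <- matrix(rnorm(n * L), n)
  expect_equal(residual_coeffs(Y, X, NULL), Y)
  expect_error(residual_coeffs(Y, X, t(beta0)), "beta0 must be")
})
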