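# Independent oracles used across the suite.  Everything here is written
# from the definitions, not by calling the implementation under test.

# trapezoid quadrature of \int f g on a grid
quad_inner <- function(f, g, grid) {
  n <- length(grid)
  w <- numeric(n)
  w[1] <- (grid[2] - grid[1]) / 2
  w[n] <- (grid[n] - grid[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (grid[3:n] - grid[1:(n - 2)]) / 2
  sum(w * f * g)
}

# least-squares projection by explicit normal equations (independent of
# the QR path used by project_curves)
normal_eq_coeffs <- function(values, Phi) {
  t(solve(crossprod(Phi), crossprod(Phi, t(values))))
}

# random symmetric Gram pair backed by actual coefficient data
random_gram_pair <- function(n, k = 3L) {
  X <- matrix(rnorm(n * k), n)
  Y <- matrix(rnorm(n * k), n)
  list(A = tcrossprod(X), B = tcrossprod(Y))
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
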