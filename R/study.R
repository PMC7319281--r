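# counter-based child seeds: reproducible per cell, independent of the
# order cells are executed in
child_seed <- function(master, index) {
  master <- as.double(master %% 2147483647)
  s <- (master * 48271 + index * 16807) %% 2147483647
  as.integer(s) + 1L
}

run_design_once <- function(design, rho, alphas) {
  if (design$response == "functional") {
    dat <- gen_functional_data(design, rho = rho)
    fit <- flute_test(dat$X, dat$Y, beta0 = NULL, alpha = alphas[1L])
  } else {
    dat <- gen_scalar_data(design, rho = rho)
    fit <- scalar_test(dat$X, dat$y, beta0 = NULL, alpha = alphas[1L])
  }
  fit$z >= stats::qnorm(1 - alphas)   # one rejection flag per alpha
}

#' Empirical size and power over a Monte-Carlo grid
#'
#' For each design cell and each signal level, simulates \code{reps}
#' independent datasets, applies the matching dependence test at each
#' nominal level and records the rejection fraction with its binomial
#' Monte-Carlo standard error.  Each cell gets its own child seed derived
#' from the master seed by a counter scheme, so single cells can be
#' reproduced independently and results do not depend on execution order.
#' Replicates whose test aborts with a calibration error are counted in
#' \code{n_errors}, never silently dropped.
#'
#' @param designs A \code{simulation_design} or a list of them (their
#'   \code{betasq} is overridden by \code{betasq_levels}).
#' @param betasq_levels Numeric vector of |beta|^2 levels (0 = size).
#' @param reps Replicates per cell; defaults to the design's \code{reps}.
#' @param seed Master seed.
#' @return A data frame of class \code{"power_table"}: one row per
#'   (cell, level, alpha) with \code{reject_rate}, \code{se},
#'   \code{reps} and \code{n_errors}.
#' @examples
#' d <- simulation_design(n = 40, K = 5, L = 5)
#' size_power_table(d, betasq_levels = c(0, 0.5), reps = 20, seed = 1)
#' @export
size_power_table <- function(designs, betasq_levels = 0, reps = NULL,
                             seed = 20200626) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  rows <- list()
  cell_index <- 0L
  for (d_i in seq_along(designs)) {
    for (b_i in seq_along(betasq_levels)) {
      cell_index <- cell_index + 1L
      design <- designs[[d_i]]
      design$betasq <- betasq_levels[b_i]
      nrep <- if (is.null(reps)) design$reps else as.integer(reps)
      alphas <- design$alpha_levels
      set.seed(child_seed(seed, cell_index))
      fixed_rho <- if (design$rho_policy == "fixed_per_cell")
        stats::runif(design$T) else NULL
      rej <- matrix(0, nrep, length(alphas))
      errors <- 0L
      for (r in seq_len(nrep)) {
        out <- tryCatch(run_design_once(design, fixed_rho, alphas),
                        error = function(e) {
                          if (grepl("calibration", conditionMessage(e)))
                            return(NULL)
                          stop(e)
                        })
        if (is.null(out)) errors <- errors + 1L else rej[r, ] <- out
      }
      ok <- nrep - errors
      for (a_i in seq_along(alphas)) {
        p_hat <- if (ok > 0) sum(rej[, a_i]) / ok else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          cell = d_i, response = design$response, n = design$n,
          K = design$K, L = design$L, T = design$T,
          error_cov = design$error_cov, betasq = design$betasq,
          alpha = alphas[a_i], reject_rate = p_hat,
          se = if (ok > 0) sqrt(p_hat * (1 - p_hat) / ok) else NA_real_,
          reps = ok, n_errors = errors,
          seed = child_seed(seed, cell_index))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Null distribution of the standardized statistic
#'
#' Simulates the design under the null (the signal level is forced to
#' zero), collects the standardized statistics z and compares them with
#' the standard normal by a Kolmogorov-Smirnov test.
#'
#' @param design A \code{simulation_design}.
#' @param reps Number of replicates.
#' @param seed Seed.
#' @return List with \code{z} (length-\code{reps} vector), \code{ks}
#'   (an \code{htest}), and the empirical rejection rate at each of the
#'   design's alpha levels.
#' @export
null_distribution_sample <- function(design, reps = 2000L, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  design$betasq <- 0
  set.seed(seed)
  fixed_rho <- if (design$rho_policy == "fixed_per_cell")
    stats::runif(design$T) else NULL
  z <- numeric(reps)
  for (r in seq_len(reps)) {
    if (design$response == "functional") {
      dat <- gen_functional_data(design, rho = fixed_rho)
      z[r] <- flute_test(dat$X, dat$Y)$z
    } else {
      dat <- gen_scalar_data(design, rho = fixed_rho)
      z[r] <- scalar_test(dat$X, dat$y)$z
    }
  }
  sizes <- vapply(design$alpha_levels,
                  function(a) mean(z >= stats::qnorm(1 - a)), 0)
  names(sizes) <- paste0("alpha_", design$alpha_levels)
  list(z = z, ks = stats::ks.test(z, "pnorm"), size = sizes)
}

#' Bootstrap distribution of the standardized statistic
#'
#' Resamples subjects with replacement and recomputes the standardized
#' statistic on each resample; resamples with fewer than 4 distinct
#' subjects are redrawn (and counted).  Under a strong signal the
#' bootstrap mass sits far in the right tail of the standard normal;
#' under the null it stays near the observed statistic's null range.
#'
#' @param X,Y Coefficient sets (Y may be a numeric vector for a scalar
#'   response).
#' @param beta0 Hypothesized surface/vector or \code{NULL}.
#' @param n_boot Number of bootstrap draws.
#' @param seed Seed.
#' @param indices Optional fixed resample index matrix
#'   (\code{n_boot} rows) for reproducibility checks.
#' @return Numeric vector of standardized statistics with attribute
#'   \code{"redraws"}.
#' @export
bootstrap_statistic_distribution <- function(X, Y, beta0 = NULL,
                                             n_boot = 1000L, seed = 1L,
                                             indices = NULL) {
  xi <- coef_matrix(X)
  scalar <- is.numeric(Y) && is.null(dim(Y))
  n <- nrow(xi)
  set.seed(seed)
  z <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    if (!is.null(indices)) {
      idx <- indices[b, ]
    } else {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 4L) break
        redraws <- redraws + 1L
      }
    }
    z[b] <- if (scalar)
      scalar_test(xi[idx, , drop = FALSE], Y[idx], beta0)$z
    else
      flute_test(xi[idx, , drop = FALSE],
                 coef_matrix(Y)[idx, , drop = FALSE], beta0)$z
  }
  attr(z, "redraws") <- redraws
  z
}
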