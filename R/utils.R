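#' Uniform container for test results
#'
#' Every resampling or rank test in the package returns a `test_result`:
#' a method name, the observed statistic, a p-value, and enough bookkeeping
#' (resample count, seed, group labels) to reproduce the run.
#'
#' @param method Character name of the test.
#' @param statistic Observed test statistic (scalar).
#' @param p_value P-value in \[0, 1\].
#' @param n_resamples Number of resamples/permutations, or `NA` for exact tests.
#' @param seed RNG seed used, or `NA`.
#' @param groups Labels of the groups compared, or `NULL`.
#' @param ... Further named components stored verbatim (e.g. post-hoc tables).
#' @return An object of class `test_result`.
#' @export
test_result <- function(method, statistic, p_value, n_resamples = NA_integer_,
                        seed = NA_integer_, groups = NULL, ...) {
  stopifnot(is.character(method), length(method) == 1L)
  if (!is.na(p_value)) stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = unname(p_value),
         n_resamples = n_resamples, seed = seed, groups = groups, ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p-value = %.4g\n", x$statistic, x$p_value))
  if (!is.na(x$n_resamples))
    cat(sprintf("  resamples = %d, seed = %s\n", x$n_resamples,
                ifelse(is.na(x$seed), "none", as.character(x$seed))))
  if (!is.null(x$groups))
    cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Each pipeline stage draws its own seed from the master seed and the stage
#' name, so adding or reordering stages never perturbs the randomness of the
#' others.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master) %% 1048573 * 2039 + h) %% 2147483647)
}

# Trapezoid quadrature weights on a (possibly non-equispaced) grid.
trapezoid_weights <- function(grid) {
  m <- length(grid)
  stopifnot(m >= 2L, all(diff(grid) > 0))
  w <- numeric(m)
  d <- diff(grid)
  w[1] <- d[1] / 2
  w[m] <- d[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (d[-1] + d[-(m - 1)]) / 2
  w
}

# Squared L2 norms of curve rows under trapezoid quadrature.
l2_norm_sq <- function(curves, grid) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1L)
  w <- trapezoid_weights(grid)
  as.numeric(curves^2 %*% w)
}

# Pairwise L2 distance matrix between curve rows (trapezoid quadrature).
l2_distance_matrix <- function(curves, grid) {
  w <- trapezoid_weights(grid)
  g <- curves %*% (w * t(curves))       # Gram matrix under the quadrature
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0                        # numeric noise
  sqrt(d2)
}
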