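#' Kernel density estimate with Sheather-Jones plug-in bandwidth
#'
#' Gaussian-kernel density with the direct plug-in bandwidth of Sheather and
#' Jones, the standard choice for fitting size distributions. The returned
#' density is non-negative and integrates to 1 over the grid.
#'
#' @param values Univariate sample (n >= 5, finite, non-degenerate).
#' @param n_grid Number of evaluation points (default 512).
#' @return List of class `kde`: `x` (grid), `y` (density), `bw` (bandwidth),
#'   `n`.
#' @export
kde_plugin <- function(values, n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("need at least 5 observations")
  if (!all(is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) stop("zero-variance sample: density undefined")
  bw <- stats::bw.SJ(values, method = "dpi")
  d <- stats::density(values, bw = bw, n = n_grid)
  structure(list(x = d$x, y = d$y, bw = bw, n = length(values)),
            class = "kde")
}

#' Kruskal-Wallis rank ANOVA across groups
#'
#' One-factor ANOVA by ranks: the H statistic with mid-rank tie correction and
#' a chi-squared (k - 1) p-value, for testing whether k independent samples
#' share a common location.
#'
#' @param ... Either k numeric vectors, a single list of them, or
#'   (`values`, `groups`) as two arguments: a numeric vector and a grouping
#'   factor of the same length.
#' @return A [test_result()] with the H statistic.
#' @export
kruskal_wallis <- function(...) {
  gl <- collect_groups(...)
  stopifnot(length(gl) >= 2L)
  if (any(vapply(gl, length, 0L) < 2L)) stop("each group needs n >= 2")
  labels <- names(gl)
  pooled <- unlist(gl, use.names = FALSE)
  if (length(unique(pooled)) == 1L)    # everything tied: no evidence, H = 0
    return(test_result("Kruskal-Wallis rank ANOVA", statistic = 0,
                       p_value = 1, groups = labels))
  kt <- stats::kruskal.test(gl)
  test_result("Kruskal-Wallis rank ANOVA",
              statistic = unname(kt$statistic),
              p_value = unname(kt$p.value),
              groups = labels)
}

# Accepts k vectors, a list, or (values, groups); returns a named list.
collect_groups <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  if (length(args) == 2L && is.numeric(args[[1]]) &&
      (is.factor(args[[2]]) || is.character(args[[2]])) &&
      length(args[[1]]) == length(args[[2]])) {
    return(split(args[[1]], args[[2]]))
  }
  if (is.null(names(args)) || any(names(args) == ""))
    names(args) <- paste0("g", seq_along(args))
  args
}

#' Tukey HSD post-hoc comparisons on rank-transformed data
#'
#' Pairwise comparisons after a rank ANOVA: the pooled sample is converted to
#' mid-ranks and Tukey's honest-significant-difference procedure (studentized
#' range quantiles) is applied to the ranks. Groups with a single observation
#' are excluded with a warning. With `on = "raw"` the comparisons are run on
#' the original scale instead.
#'
#' @inheritParams kruskal_wallis
#' @param on `"ranks"` (default) or `"raw"`.
#' @return Data frame: one row per pair, with `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd_on_ranks <- function(..., on = c("ranks", "raw")) {
  on <- match.arg(on)
  gl <- collect_groups(...)
  sizes <- vapply(gl, length, 0L)
  if (any(sizes < 2L)) {
    warning("excluding group(s) with n = 1: ",
            paste(names(gl)[sizes < 2L], collapse = ", "))
    gl <- gl[sizes >= 2L]
  }
  if (length(gl) < 2L) stop("need at least 2 groups with n >= 2")
  values <- unlist(gl, use.names = FALSE)
  g <- factor(rep(names(gl), vapply(gl, length, 0L)), levels = names(gl))
  y <- if (on == "ranks") rank(values) else values
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit)$g
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "on") <- on
  out
}

#' Distance-based test for homogeneity of group dispersions
#'
#' A permutation test of whether groups differ in spread rather than location:
#' each observation is reduced to its distance from its own group centroid
#' (absolute deviation from the group mean for univariate data, Euclidean
#' distance to the centroid for multivariate rows), a one-way ANOVA F is
#' computed on those distances, and its null distribution is obtained by
#' permuting group labels over the distances. Because distances are
#' centroid-relative, the test is invariant to group-specific location shifts.
#' Tukey HSD on the distances provides post-hoc pairwise comparisons.
#'
#' @param values Numeric vector (univariate) or matrix (rows = observations).
#' @param groups Grouping factor (k >= 2 groups, each n >= 3).
#' @param n_perm Number of label permutations (default 999; < 199 warns).
#' @param seed Integer seed.
#' @param centroid `"mean"` (default) or `"median"` per-group centroid.
#' @return A [test_result()] with the F statistic, permutation p-value
#'   (+1-corrected), and components `distances` and `posthoc`.
#' @export
dispersion_test <- function(values, groups, n_perm = 999L, seed = NULL,
                            centroid = c("mean", "median")) {
  centroid <- match.arg(centroid)
  g <- factor(groups)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  stopifnot(nrow(values) == length(g))
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L)) stop("each group needs n >= 3")
  if (n_perm < 199L) warning("n_perm < 199: permutation p-value is coarse")
  cent_fun <- if (centroid == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  d <- numeric(nrow(values))
  for (lev in levels(g)) {
    idx <- g == lev
    ctr <- cent_fun(values[idx, , drop = FALSE])
    d[idx] <- sqrt(rowSums(sweep(values[idx, , drop = FALSE], 2L, ctr)^2))
  }
  f_obs <- anova_f(d, g)
  if (!is.finite(f_obs)) {                 # all distances identical
    return(test_result("Distance-based dispersion test (permutation)",
                       statistic = 0, p_value = 1,
                       n_resamples = as.integer(n_perm), seed = seed,
                       groups = levels(g), distances = d, posthoc = NULL))
  }
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(b) anova_f(d, g[sample.int(length(g))]), 0)
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  posthoc <- tryCatch(tukey_hsd_on_ranks(d, as.character(g), on = "raw"),
                      error = function(e) NULL)
  test_result("Distance-based dispersion test (permutation)",
              statistic = f_obs, p_value = p,
              n_resamples = as.integer(n_perm), seed = seed,
              groups = levels(g), distances = d, posthoc = posthoc)
}

# One-way ANOVA F via group sums; NA/NaN when the within-group SS is zero.
anova_f <- function(y, g) {
  n <- length(y); k <- nlevels(g)
  sums <- tapply(y, g, sum)
  ns <- tabulate(g)
  ssb <- sum(sums^2 / ns) - sum(y)^2 / n
  ssw <- sum(y^2) - sum(sums^2 / ns)
  if (ssw <= .Machine$double.eps * sum(y^2 + 1)) return(NaN)
  (ssb / (k - 1)) / (ssw / (n - k))
}
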