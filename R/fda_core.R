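#' Nadaraya-Watson kernel smoother for an individual trajectory
#'
#' Estimates the underlying continuous curve X(t) from discrete, possibly
#' irregular and partially missing observations by locally weighted averaging:
#' X(t) = sum_j y_j K_h(t - t_j) / sum_j K_h(t - t_j), with K the standard
#' Gaussian kernel and K_h(u) = K(u/h)/h. The estimate is a convex combination
#' of the observations, so it always lies within their range, and the weights
#' at every evaluation point sum to one.
#'
#' @param t Observation times (days).
#' @param y Observed values (same length as `t`; `NA`s are dropped from the
#'   kernel sums, no imputation).
#' @param h Bandwidth in days (> 0).
#' @param grid Evaluation times.
#' @return Numeric vector of smoothed values on `grid`.
#' @export
nw_smooth <- function(t, y, h, grid) {
  stopifnot(length(t) == length(y))
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0)
    stop("bandwidth 'h' must be a single positive number")
  keep <- !is.na(y) & !is.na(t)
  if (!any(keep)) stop("trajectory has no non-missing observations")
  t <- t[keep]; y <- y[keep]
  k <- stats::dnorm(outer(grid, t, "-") / h)
  sw <- rowSums(k)
  out <- as.numeric(k %*% y) / sw
  # Gaussian weights can underflow far from the data at tiny h: fall back to
  # the nearest observation (the smoother's own limit as weights vanish).
  bad <- !is.finite(out)
  if (any(bad)) {
    nearest <- vapply(grid[bad], function(g) y[which.min(abs(t - g))], 0)
    out[bad] <- nearest
  }
  out
}

# Smoother (hat) matrix of the NW estimator on the observation times.
nw_smoother_matrix <- function(t, h) {
  k <- stats::dnorm(outer(t, t, "-") / h)
  k / rowSums(k)
}

#' Generalized cross-validation bandwidth selection
#'
#' Scores each candidate bandwidth by
#' GCV(h) = (1/n) sum_i \[(y_i - X_h(t_i)) / (1 - tr(S_h)/n)\]^2,
#' where S_h is the Nadaraya-Watson smoother matrix on the observation times,
#' and returns the candidate minimising it. Ties (including the all-zero GCV
#' of noiseless constant data) are broken toward the largest candidate, i.e.
#' toward the smoother fit.
#'
#' @param t Observation times.
#' @param y Observed values (`NA`s dropped).
#' @param candidates Candidate bandwidths (> 0); default
#'   [default_bandwidth_grid()] on the non-missing times.
#' @return The selected bandwidth, with attribute `gcv`: the GCV score of
#'   every candidate.
#' @export
gcv_bandwidth <- function(t, y, candidates = NULL) {
  stopifnot(length(t) == length(y))
  keep <- !is.na(y) & !is.na(t)
  t <- t[keep]; y <- y[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 non-missing points for GCV")
  if (is.null(candidates)) candidates <- default_bandwidth_grid(t)
  if (length(candidates) == 0L || any(candidates <= 0))
    stop("'candidates' must be a non-empty set of positive bandwidths")
  candidates <- sort(candidates)
  scores <- vapply(candidates, function(h) {
    s <- nw_smoother_matrix(t, h)
    denom <- 1 - sum(diag(s)) / n
    if (!is.finite(denom) || denom <= .Machine$double.eps) return(Inf)
    mean(((y - as.numeric(s %*% y)) / denom)^2)
  }, 0)
  if (all(!is.finite(scores)))
    stop("GCV non-finite for every candidate bandwidth")
  best <- min(scores[is.finite(scores)])
  tol <- 1e-12 * max(best, 1)
  h_star <- candidates[max(which(scores <= best + tol))]
  structure(h_star, gcv = stats::setNames(scores, signif(candidates, 6)))
}

#' Default candidate bandwidth grid
#'
#' 25 log-spaced values from half the smallest gap between observation times
#' (near-interpolation) to the full time span (near-flat), bracketing the
#' useful range of the Gaussian kernel smoother.
#'
#' @param t Observation times (>= 3 distinct values).
#' @param length_out Number of candidates (default 25).
#' @return Numeric vector of bandwidths.
#' @export
default_bandwidth_grid <- function(t, length_out = 25L) {
  tt <- sort(unique(t[!is.na(t)]))
  if (length(tt) < 2L) stop("need at least 2 distinct times")
  lo <- min(diff(tt)) / 2
  hi <- diff(range(tt))
  exp(seq(log(lo), log(hi), length.out = length_out))
}

#' Functional sample: smoothed curves on a common grid
#'
#' Container for a set of curves evaluated on a shared grid, with per-curve
#' bandwidths and identifiers. Build one from raw trajectories with
#' [build_functional_sample()], or wrap an existing matrix directly.
#'
#' @param grid Strictly increasing evaluation times.
#' @param curves Numeric matrix, one row per curve, `length(grid)` columns.
#' @param ids Row identifiers (default `1:n`).
#' @param bandwidths Per-curve bandwidths (optional).
#' @param variable Name of the measured variable (optional).
#' @param skipped Data frame describing excluded trajectories (optional).
#' @return An object of class `functional_sample`.
#' @export
functional_sample <- function(grid, curves, ids = NULL, bandwidths = NULL,
                              variable = NA_character_, skipped = NULL) {
  curves <- as.matrix(curves)
  stopifnot(is.numeric(grid), all(diff(grid) > 0),
            ncol(curves) == length(grid))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(curves)))
  stopifnot(length(ids) == nrow(curves))
  if (!is.null(bandwidths)) stopifnot(length(bandwidths) == nrow(curves),
                                      all(bandwidths > 0))
  if (is.null(skipped))
    skipped <- data.frame(individual_id = character(0), reason = character(0))
  rownames(curves) <- ids
  structure(list(grid = grid, curves = curves, ids = as.character(ids),
                 bandwidths = bandwidths, variable = variable,
                 skipped = skipped),
            class = "functional_sample")
}

#' @export
print.functional_sample <- function(x, ...) {
  cat(sprintf("Functional sample: %d curves (%s) on %d grid points over [%g, %g] days\n",
              nrow(x$curves),
              ifelse(is.na(x$variable), "unnamed variable", x$variable),
              length(x$grid), min(x$grid), max(x$grid)))
  if (nrow(x$skipped) > 0)
    cat("  skipped:", paste(x$skipped$individual_id, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.functional_sample <- function(x, col = "grey40", ...) {
  graphics::matplot(x$grid, t(x$curves), type = "l", lty = 1, col = col,
                    xlab = "time (days)",
                    ylab = ifelse(is.na(x$variable), "value", x$variable), ...)
  invisible(x)
}

#' Build a functional sample from long-format trajectories
#'
#' For each individual, selects a bandwidth by GCV and evaluates its
#' Nadaraya-Watson curve on a common equispaced grid spanning the pooled time
#' range. Trajectories with fewer than 3 non-missing points cannot be smoothed
#' and are excluded with a warning; they are listed in the result's `skipped`
#' report. Row order follows first appearance in the input.
#'
#' @param data Data frame with columns `individual_id`, `t`, and the value
#'   column named by `value_col`.
#' @param value_col Name of the value column (default `"y"`).
#' @param grid_size Number of common grid points (default 101).
#' @param bw_candidates Candidate bandwidths passed to [gcv_bandwidth()];
#'   default: per-trajectory [default_bandwidth_grid()].
#' @return A [functional_sample()].
#' @export
build_functional_sample <- function(data, value_col = "y", grid_size = 101L,
                                    bw_candidates = NULL) {
  stopifnot(all(c("individual_id", "t", value_col) %in% names(data)))
  ids <- unique(as.character(data$individual_id))
  tt <- data$t[!is.na(data[[value_col]])]
  if (length(tt) == 0L) stop("no non-missing observations in 'data'")
  grid <- seq(min(tt), max(tt), length.out = grid_size)
  curves <- list(); bws <- numeric(0); kept <- character(0)
  skipped <- data.frame(individual_id = character(0), reason = character(0))
  for (id in ids) {
    rows <- data[data$individual_id == id, ]
    rows <- rows[order(rows$t), ]
    y <- rows[[value_col]]; t <- rows$t
    n_ok <- sum(!is.na(y) & !is.na(t))
    if (n_ok < 3L) {
      skipped <- rbind(skipped, data.frame(
        individual_id = id,
        reason = sprintf("only %d non-missing point(s); >= 3 required", n_ok)))
      next
    }
    h <- gcv_bandwidth(t, y, bw_candidates)
    curves[[id]] <- nw_smooth(t, y, h, grid)
    bws <- c(bws, as.numeric(h)); kept <- c(kept, id)
  }
  if (nrow(skipped) > 0)
    warning("excluded ", nrow(skipped),
            " trajectory(ies) with fewer than 3 points: ",
            paste(skipped$individual_id, collapse = ", "))
  if (length(kept) < 2L) stop("fewer than 2 smoothable trajectories")
  functional_sample(grid, do.call(rbind, curves), ids = kept,
                    bandwidths = bws, skipped = skipped)
}

#' h-modal depth of each curve
#'
#' Depth of curve x_i is its total kernel similarity to the sample,
#' depth(x_i) = sum_j K(||x_i - x_j|| / h_d), with the L2 distance computed by
#' trapezoid quadrature on the grid, K the standard Gaussian kernel, and h_d
#' the 15th percentile of the pairwise distances. Curves near the functional
#' mode score high; isolated curves score low. The ordering is invariant to
#' adding a common curve to every row and to a joint positive rescaling.
#'
#' @param fs A [functional_sample()] (>= 2 curves).
#' @param h_quantile Quantile of pairwise distances used as the depth kernel
#'   bandwidth (default 0.15).
#' @return Named numeric vector of depths (one per curve).
#' @export
modal_depth <- function(fs, h_quantile = 0.15) {
  stopifnot(inherits(fs, "functional_sample"), nrow(fs$curves) >= 2L)
  d <- l2_distance_matrix(fs$curves, fs$grid)
  modal_depth_from_dist(d, fs$ids, h_quantile)
}

modal_depth_from_dist <- function(d, ids = NULL, h_quantile = 0.15) {
  n <- nrow(d)
  off <- d[upper.tri(d)]
  h_d <- stats::quantile(off, h_quantile, names = FALSE)
  if (h_d <= 0) {
    pos <- off[off > 0]
    if (length(pos) == 0L)                      # all curves identical
      return(stats::setNames(rep(n * stats::dnorm(0), n), ids))
    h_d <- min(pos)
  }
  stats::setNames(colSums(stats::dnorm(d / h_d)), ids)
}

#' Functional outlier detection by modal depth with a smoothed bootstrap cutoff
#'
#' Iteratively flags curves whose h-modal depth falls below a bootstrap
#' cutoff. B resamples of the sample are drawn from its central part and
#' smoothed with Gaussian noise whose covariance is `gamma` times the sample
#' covariance of the curves; the cutoff estimates the `alpha_cut` quantile of
#' the null depth distribution. Flagged curves are removed and the procedure
#' repeats until no curve is flagged or `max_iter` is reached. Deterministic
#' given `seed`.
#'
#' Two cutoff schemes are available. `"weighted"` (default) resamples curves
#' with probability proportional to their depth and takes the `alpha_cut`
#' quantile of all B x n bootstrap depths pooled; it holds the null flag rate
#' near `alpha_cut`. `"trimmed"` resamples uniformly from the (1 - trim)
#' deepest curves and takes the median of the per-replicate `alpha_cut`
#' quantiles; it is noticeably more liberal in moderate samples because the
#' hard trim removes the left tail of the depth distribution that the noise
#' cannot rebuild.
#'
#' @param fs A [functional_sample()] with at least 10 curves.
#' @param trim Trimming fraction in (0, 0.5) for the `"trimmed"` scheme;
#'   default 0.1 (10% trimmed mode).
#' @param B Bootstrap replicates (default 200; < 100 warns).
#' @param alpha_cut Depth quantile defining the cutoff (default 0.01).
#' @param gamma Smoothed-bootstrap noise variance as a fraction of the curve
#'   covariance (default 0.05).
#' @param method Cutoff scheme: `"weighted"` (default) or `"trimmed"`.
#' @param max_iter Maximum flag-and-repeat iterations (default 5).
#' @param seed Integer seed (required for reproducibility).
#' @return Object of class `depth_result`: `depths` (initial depths, all
#'   curves), `cutoff` (initial cutoff), `outlier_ids`, `history` (one row per
#'   flagged curve: iteration, id, depth and the cutoff that flagged it),
#'   `iterations`, `converged`, `B`, `seed`.
#' @export
trimmed_mode_outliers <- function(fs, trim = 0.1, B = 200L, alpha_cut = 0.01,
                                  gamma = 0.05,
                                  method = c("weighted", "trimmed"),
                                  max_iter = 5L, seed) {
  method <- match.arg(method)
  stopifnot(inherits(fs, "functional_sample"))
  n <- nrow(fs$curves)
  if (n < 10L) stop("outlier detection needs at least 10 curves")
  stopifnot(trim > 0, trim < 0.5, gamma >= 0)
  if (B < 100L) warning("B < 100 bootstrap replicates: cutoff may be unstable")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  m <- ncol(fs$curves)
  active <- seq_len(n)
  history <- data.frame(iteration = integer(0), individual_id = character(0),
                        depth = numeric(0), cutoff = numeric(0))
  depths0 <- NULL; cutoff0 <- NULL
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- fs$curves[active, , drop = FALSE]
    nc <- nrow(cur)
    dep <- modal_depth_from_dist(l2_distance_matrix(cur, fs$grid))
    all_equal <- diff(range(dep)) <= 1e-12 * max(abs(dep))
    if (all_equal) {                       # identical curves: nothing to flag
      if (iter == 1L) { depths0 <- dep; cutoff0 <- -Inf }
      converged <- TRUE
      break
    }
    # smoothed-bootstrap noise ~ N(0, gamma * cov(curves))
    sig <- stats::cov(cur) * gamma
    ei <- eigen(sig, symmetric = TRUE)
    amat <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), m)
    if (method == "weighted") {
      pool <- cur
      prob <- dep / sum(dep)
      boot_dep <- lapply(seq_len(B), function(b) {
        idx <- sample.int(nc, nc, replace = TRUE, prob = prob)
        bs <- pool[idx, , drop = FALSE] +
          t(amat %*% matrix(stats::rnorm(nc * m), m, nc))
        modal_depth_from_dist(l2_distance_matrix(bs, fs$grid))
      })
      cutoff <- stats::quantile(unlist(boot_dep), alpha_cut, names = FALSE)
    } else {
      keep <- order(dep, decreasing = TRUE)[seq_len(ceiling((1 - trim) * nc))]
      pool <- cur[keep, , drop = FALSE]
      qs <- vapply(seq_len(B), function(b) {
        idx <- sample.int(nrow(pool), nc, replace = TRUE)
        bs <- pool[idx, , drop = FALSE] +
          t(amat %*% matrix(stats::rnorm(nc * m), m, nc))
        stats::quantile(modal_depth_from_dist(l2_distance_matrix(bs, fs$grid)),
                        alpha_cut, names = FALSE)
      }, 0)
      cutoff <- stats::median(qs)
    }
    if (iter == 1L) { depths0 <- dep; cutoff0 <- cutoff }
    new <- which(dep < cutoff)
    if (length(new) == 0L) { converged <- TRUE; break }
    history <- rbind(history, data.frame(
      iteration = iter, individual_id = fs$ids[active[new]],
      depth = dep[new], cutoff = cutoff))
    active <- active[-new]
    if (length(active) < 10L) break
  }
  if (!converged && iter >= max_iter)
    warning("outlier procedure did not converge in ", max_iter, " iterations")
  structure(list(
    depths = stats::setNames(depths0, fs$ids),
    cutoff = cutoff0,
    outlier_ids = history$individual_id,
    history = history,
    iterations = iter, converged = converged,
    B = as.integer(B), seed = as.integer(seed)),
    class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  cat(sprintf("Trimmed-mode depth outlier scan: %d curve(s) flagged of %d (B = %d, seed = %d)\n",
              length(x$outlier_ids), length(x$depths), x$B, x$seed))
  if (length(x$outlier_ids) > 0)
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Pointwise mean curve of a functional sample
#'
#' @param fs A [functional_sample()].
#' @return Numeric vector: the mean curve on `fs$grid`.
#' @export
functional_mean <- function(fs) {
  stopifnot(inherits(fs, "functional_sample"))
  colMeans(fs$curves)
}

#' Uniform bootstrap confidence band for the mean curve
#'
#' Resamples curves with replacement B times; the band radius is the `level`
#' quantile of the sup-norm deviation of the resampled means from the observed
#' mean, giving a band with simultaneous (uniform over t) coverage. The band
#' always contains the observed mean.
#'
#' @param fs A [functional_sample()] (>= 2 curves).
#' @param B Bootstrap replicates (default 500; >= 200 recommended).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return List with `mean`, `lower`, `upper` (curves on `fs$grid`),
#'   `radius`, `level`, `B`, `seed`.
#' @export
bootstrap_band <- function(fs, B = 500L, level = 0.95, seed) {
  stopifnot(inherits(fs, "functional_sample"), nrow(fs$curves) >= 2L)
  if (B < 200L) warning("B < 200: band quantile may be unstable")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n <- nrow(fs$curves)
  mu <- colMeans(fs$curves)
  dev <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    max(abs(colMeans(fs$curves[idx, , drop = FALSE]) - mu))
  }, 0)
  r <- stats::quantile(dev, level, names = FALSE)
  list(mean = mu, lower = mu - r, upper = mu + r, radius = r,
       level = level, B = as.integer(B), seed = as.integer(seed))
}
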