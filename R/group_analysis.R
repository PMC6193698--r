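#' Select individuals with a common starting size
#'
#' Returns the ids whose first-sampling value of `variable` lies within
#' `target` +/- `tolerance`, emulating the selection of an even-sized
#' subsample at the start of monitoring so that later group differences are
#' not confounded by initial size.
#'
#' @param records Measurement data frame (columns `individual_id`, `t`, and
#'   `variable`).
#' @param variable Column to select on (default `"L"`).
#' @param target Target starting value (e.g. 21 mm).
#' @param tolerance Half-width of the acceptance window (same units).
#' @return Character vector of selected ids.
#' @export
select_even_start <- function(records, variable = "L", target, tolerance) {
  stopifnot(all(c("individual_id", "t", variable) %in% names(records)))
  t0 <- min(records$t)
  first <- records[records$t == t0, ]
  v <- first[[variable]]
  sel <- !is.na(v) & abs(v - target) <= tolerance + 1e-9
  ids <- as.character(first$individual_id[sel])
  if (length(ids) == 0L)
    stop("no individual within ", target, " +/- ", tolerance,
         " at first sampling; widen the tolerance")
  ids
}

#' Classify individuals into fast and slow growers by final-size median split
#'
#' Computes the median of the final-sampling values and labels individuals
#' strictly above it "fast" and strictly below it "slow". Individuals exactly
#' at the median belong to neither group: they are excluded and listed in the
#' `excluded` attribute.
#'
#' @param records Measurement data frame (columns `individual_id`, `t`, and
#'   `criterion`).
#' @param criterion Size variable defining the split: `"L"` or `"TFW"`
#'   (any numeric column works).
#' @return Data frame of class `group_labels`: `individual_id`, `criterion`,
#'   `label` ("fast"/"slow"), `cutpoint`; attributes `excluded` (ids at the
#'   median) and `cutpoint`.
#' @export
classify_growers <- function(records, criterion = c("L", "TFW")) {
  if (is.character(criterion) && length(criterion) > 1L)
    criterion <- match.arg(criterion)
  stopifnot(all(c("individual_id", "t", criterion) %in% names(records)))
  t_final <- max(records$t)
  final <- records[records$t == t_final, ]
  final <- final[!is.na(final[[criterion]]), ]
  if (nrow(final) < 4L) stop("need at least 4 individuals with a final value")
  v <- final[[criterion]]
  med <- stats::median(v)
  at <- abs(v - med) <= 1e-9
  fast <- v > med & !at
  slow <- v < med & !at
  if (sum(fast) < 1L || sum(slow) < 1L)
    stop("median split leaves an empty group")
  if (sum(fast) < 2L || sum(slow) < 2L)
    warning("median split leaves a single individual in a group")
  if (any(at))
    message(sum(at), " individual(s) exactly at the median excluded: ",
            paste(final$individual_id[at], collapse = ", "))
  out <- data.frame(
    individual_id = as.character(final$individual_id[!at]),
    criterion = criterion,
    label = ifelse(fast[!at], "fast", "slow"),
    cutpoint = med,
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- as.character(final$individual_id[at])
  attr(out, "cutpoint") <- med
  class(out) <- c("group_labels", class(out))
  out
}

#' One-way functional ANOVA with a Gaussian-process bootstrap null
#'
#' Tests equality of group mean curves with the statistic
#' V = sum_{i<j} n_i ||Xbar_i - Xbar_j||^2 (L2 norm by trapezoid quadrature on
#' the common grid). The null distribution is approximated by a parametric
#' bootstrap: each group's mean curve is simulated B times as a zero-mean
#' Gaussian process with the group's estimated pointwise covariance scaled by
#' 1/n_i, and V is recomputed; p = (1 + #\{V_b >= V\}) / (1 + B).
#' A label-permutation null is available via `null = "permutation"` as a
#' robustness check.
#'
#' @param fs A [functional_sample()].
#' @param labels Group labels: a factor/character vector aligned with
#'   `fs$ids`, or a [classify_growers()] result (matched by id; curves without
#'   a label are dropped).
#' @param B Number of bootstrap resamples (default 500; < 200 warns).
#' @param seed Integer seed.
#' @param null `"bootstrap"` (default) or `"permutation"`.
#' @return A [test_result()] with statistic V and component `group_means`.
#' @export
fanova <- function(fs, labels, B = 500L, seed, null = c("bootstrap",
                                                        "permutation")) {
  null <- match.arg(null)
  stopifnot(inherits(fs, "functional_sample"))
  if (missing(seed)) stop("'seed' is required")
  if (B < 200L) warning("B < 200 resamples: p-value is coarse")
  if (inherits(labels, "group_labels") || is.data.frame(labels)) {
    lab <- labels$label[match(fs$ids, labels$individual_id)]
  } else {
    stopifnot(length(labels) == length(fs$ids))
    lab <- as.character(labels)
  }
  keep <- !is.na(lab)
  curves <- fs$curves[keep, , drop = FALSE]
  g <- factor(lab[keep])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L)) stop("each group needs at least 3 curves")
  grid <- fs$grid
  ns <- as.numeric(table(g))
  means <- lapply(levels(g), function(lev)
    colMeans(curves[g == lev, , drop = FALSE]))
  v_stat <- function(mm) {
    v <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      v <- v + ns[i] * l2_norm_sq(mm[[i]] - mm[[j]], grid)
    v
  }
  v_obs <- v_stat(means)
  set.seed(seed)
  if (null == "bootstrap") {
    # per-group Gaussian-process samplers for the mean curve:
    # Xbar_i* ~ GP(0, K_i / n_i), via eigen-decomposition of K_i
    samplers <- lapply(seq_len(k), function(i) {
      kc <- stats::cov(curves[g == levels(g)[i], , drop = FALSE]) / ns[i]
      e <- eigen(kc, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      a <- e$vectors %*% diag(sqrt(lam), length(lam))
      function() as.numeric(a %*% stats::rnorm(length(lam)))
    })
    v_null <- vapply(seq_len(B), function(b)
      v_stat(lapply(samplers, function(f) f())), 0)
  } else {
    v_null <- vapply(seq_len(B), function(b) {
      gp <- g[sample.int(length(g))]
      v_stat(lapply(levels(g), function(lev)
        colMeans(curves[gp == lev, , drop = FALSE])))
    }, 0)
  }
  p <- (1 + sum(v_null >= v_obs)) / (1 + B)
  test_result(paste0("One-way functional ANOVA (",
                     ifelse(null == "bootstrap",
                            "Gaussian-process bootstrap", "permutation"),
                     ")"),
              statistic = v_obs, p_value = p, n_resamples = as.integer(B),
              seed = as.integer(seed), groups = levels(g),
              group_means = stats::setNames(means, levels(g)),
              group_sizes = stats::setNames(ns, levels(g)))
}

#' Distance-covariance test of dependence between two curve sets
#'
#' Measures dependence between two functional samples observed on the same
#' individuals with the (squared) distance covariance computed from their
#' pairwise L2 distance matrices, and tests independence by permuting the
#' pairing of one sample's individuals. Sensitive to nonlinear as well as
#' linear association between the curve sets.
#'
#' @param fsX,fsY [functional_sample()]s with identical ids in identical
#'   order.
#' @param n_perm Number of pairing permutations (default 999).
#' @param seed Integer seed.
#' @return A [test_result()] with the dCov^2 V-statistic.
#' @export
functional_correlation_test <- function(fsX, fsY, n_perm = 999L, seed) {
  stopifnot(inherits(fsX, "functional_sample"),
            inherits(fsY, "functional_sample"))
  if (missing(seed)) stop("'seed' is required")
  if (!identical(fsX$ids, fsY$ids))
    stop("the two samples must hold the same individuals in the same order")
  n <- nrow(fsX$curves)
  dc <- function(d) {
    sweep(sweep(d, 1L, rowMeans(d)), 2L, colMeans(d)) + mean(d)
  }
  a <- dc(l2_distance_matrix(fsX$curves, fsX$grid))
  b <- dc(l2_distance_matrix(fsY$curves, fsY$grid))
  v_obs <- mean(a * b)
  set.seed(seed)
  v_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    mean(a * b[p, p])
  }, 0)
  p <- (1 + sum(v_perm >= v_obs)) / (1 + n_perm)
  test_result("Functional distance-covariance test (permutation)",
              statistic = v_obs, p_value = p,
              n_resamples = as.integer(n_perm), seed = as.integer(seed))
}

#' Group-comparison report: functional ANOVA table with mean curves and bands
#'
#' The full fast/slow comparison workflow: on an even-start subsample, split
#' individuals by the final median of each criterion (shell length and total
#' fresh weight), then for every variable run a functional ANOVA between the
#' groups and compute group mean curves with uniform bootstrap bands. The
#' result mirrors a two-criteria-by-nine-variables comparison table.
#'
#' @param derived Enriched measurement data frame (output of [derive_all()]).
#' @param criteria Size variables defining the splits (default
#'   `c("L", "TFW")`).
#' @param variables Variables to compare (default the nine growth, feeding,
#'   digestion and metabolic measures).
#' @param ids Optional subset of individual ids to analyse (e.g. the
#'   even-start subsample with outliers removed).
#' @param grid_size Common grid size for smoothing (default 101).
#' @param B Functional-ANOVA resamples (default 500).
#' @param B_band Bootstrap-band resamples (default 500).
#' @param seed Integer master seed for the report.
#' @return List of class `group_report`: `table` (one row per criterion x
#'   variable: n per group, statistic, p_value, note) and `curves` (nested
#'   list of per-group mean curves and bands).
#' @export
compare_groups_report <- function(derived, criteria = c("L", "TFW"),
                                  variables = c("L", "TFW", "SFG", "CR",
                                                "OIR", "AE", "AR", "VO2",
                                                "VNH4"),
                                  ids = NULL, grid_size = 101L, B = 500L,
                                  B_band = 500L, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(ids)) derived <- derived[derived$individual_id %in% ids, ]
  rows <- list(); curves <- list()
  for (crit in criteria) {
    labels <- classify_growers(derived, crit)
    curves[[crit]] <- list()
    for (v in variables) {
      s_fan <- derive_seed(seed, paste("fanova", crit, v))
      note <- ""
      res <- tryCatch({
        long <- derived[, c("individual_id", "t")]
        long$y <- derived[[v]]
        fs <- suppressWarnings(build_functional_sample(long, "y", grid_size))
        fit <- fanova(fs, labels, B = B, seed = s_fan)
        fast_ids <- labels$individual_id[labels$label == "fast"]
        fs_fast <- subset_fs(fs, fs$ids %in% fast_ids)
        fs_slow <- subset_fs(fs, !(fs$ids %in% fast_ids) &
                               fs$ids %in% labels$individual_id)
        curves[[crit]][[v]] <- list(
          grid = fs$grid,
          fast = bootstrap_band(fs_fast, B = B_band, seed = s_fan + 1L),
          slow = bootstrap_band(fs_slow, B = B_band, seed = s_fan + 2L))
        list(stat = fit$statistic, p = fit$p_value,
             n_fast = fit$group_sizes[["fast"]],
             n_slow = fit$group_sizes[["slow"]])
      }, error = function(e) {
        note <<- conditionMessage(e)
        list(stat = NA_real_, p = NA_real_, n_fast = NA_real_,
             n_slow = NA_real_)
      })
      rows[[paste(crit, v)]] <- data.frame(
        criterion = crit, variable = v,
        n_fast = res$n_fast, n_slow = res$n_slow,
        statistic = res$stat, p_value = res$p,
        B = as.integer(B), seed = s_fan,
        note = ifelse(nchar(note) > 0, paste("not computed:", note), ""),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 curves = curves, seed = as.integer(seed)),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("Fast vs slow grower functional ANOVA report\n")
  print(x$table[, c("criterion", "variable", "n_fast", "n_slow",
                    "statistic", "p_value", "note")], row.names = FALSE)
  invisible(x)
}

# Row-subset of a functional sample, keeping grid and metadata.
subset_fs <- function(fs, which_rows) {
  functional_sample(fs$grid, fs$curves[which_rows, , drop = FALSE],
                    ids = fs$ids[which_rows],
                    bandwidths = if (!is.null(fs$bandwidths))
                      fs$bandwidths[which_rows],
                    variable = fs$variable)
}
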