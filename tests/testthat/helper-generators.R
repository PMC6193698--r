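# Shared simulation helpers: Gaussian-process curve samples and a small
# random-measurement generator. All take explicit seeds.

gp_functional_sample <- function(n, m = 25L, seed = NULL,
                                 kernel = c("rbf", "ou"),
                                 span = c(0, 150), ell = 40) {
  kernel <- match.arg(kernel)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(span[1], span[2], length.out = m)
  K <- switch(kernel,
              rbf = outer(grid, grid, function(a, b) exp(-(a - b)^2 / (2 * ell^2))),
              ou  = outer(grid, grid, function(a, b) exp(-abs(a - b) / ell)))
  e <- eigen(K, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m)
  curves <- t(A %*% matrix(stats::rnorm(m * n), m, n))
  functional_sample(grid, curves)
}

random_records <- function(n, seed) {
  if (n == 0L) return(random_records(1L, seed)[0, ])
  set.seed(seed)
  data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    tank_id = "T1",
    t = 0,
    L = runif(n, 15, 40), TFW = runif(n, 0.3, 5),
    CR = runif(n, 0, 5), AE = runif(n, 0, 1),
    VO2 = runif(n, 0, 1), VNH4 = runif(n, 0, 20),
    stringsAsFactors = FALSE)
}

# Independent naive GCV scan (loops, no shared code path with the package).
oracle_gcv <- function(t, y, candidates) {
  n <- length(y)
  scores <- sapply(candidates, function(h) {
    fit <- numeric(n); trS <- 0
    for (i in seq_len(n)) {
      w <- exp(-0.5 * ((t[i] - t) / h)^2)
      fit[i] <- sum(w * y) / sum(w)
      trS <- trS + w[i] / sum(w)
    }
    den <- 1 - trS / n
    if (den <= .Machine$double.eps) return(Inf)
    mean(((y - fit) / den)^2)
  })
  best <- min(scores[is.finite(scores)])
  sort(candidates)[max(which(scores[order(candidates)] <= best + 1e-12 * max(best, 1)))]
}

# Hand Kruskal-Wallis with mid-rank tie correction.
oracle_kruskal <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  rb <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(ns * (rb - (N + 1) / 2)^2)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Naive modal depth: explicit loops for trapezoid L2 distances + kernel sums.
oracle_modal_depth <- function(curves, grid) {
  n <- nrow(curves); m <- length(grid)
  w <- numeric(m)
  d <- diff(grid)
  w[1] <- d[1] / 2; w[m] <- d[m - 1] / 2
  if (m > 2) for (j in 2:(m - 1)) w[j] <- (grid[j + 1] - grid[j - 1]) / 2
  dist <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dist[i, j] <- sqrt(sum(w * (curves[i, ] - curves[j, ])^2))
  h_d <- stats::quantile(dist[upper.tri(dist)], 0.15, names = FALSE)
  if (h_d <= 0) h_d <- min(dist[dist > 0])
  sapply(seq_len(n), function(i) sum(stats::dnorm(dist[i, ] / h_d)))
}
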