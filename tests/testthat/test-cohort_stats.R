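# Independent two-stage direct-plug-in bandwidth (Sheather-Jones family),
# written from the textbook formulas with explicit Gaussian-derivative sums.
oracle_dpi_bandwidth <- function(x) {
  n <- length(x)
  s <- min(sd(x), IQR(x) / 1.349)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * dnorm(u)
  psi8 <- 105 / (32 * sqrt(pi) * s^9)
  g6 <- (30 * dnorm(0) / (psi8 * n))^(1 / 9)
  dd <- outer(x, x, "-")
  psi6 <- sum(phi6(dd / g6)) / (n^2 * g6^7)
  g4 <- (-6 * dnorm(0) / (psi6 * n))^(1 / 7)
  psi4 <- sum(phi4(dd / g4)) / (n^2 * g4^5)
  (1 / (2 * sqrt(pi) * psi4 * n))^(1 / 5)
}

test_that("plug-in KDE integrates to one and matches the plug-in formula", {
  set.seed(42)
  x <- rnorm(200)
  k <- kde_plugin(x)
  expect_true(all(k$y >= 0))
  area <- sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)
  expect_lt(abs(area - 1), 1e-3)
  expect_lt(abs(k$bw - oracle_dpi_bandwidth(x)) / oracle_dpi_bandwidth(x), 0.25)
  expect_error(kde_plugin(rep(1, 10)), "variance")
  expect_error(kde_plugin(c(1, 2)), "at least 5")
})

test_that("rank ANOVA reproduces closed-form H values and handles ties", {
  expect_equal(kruskal_wallis(c(1, 2), c(3, 4))$statistic, 2.4)
  expect_equal(kruskal_wallis(c(1, 2, 3), c(4, 5, 6))$statistic, 27 / 7)
  ident <- kruskal_wallis(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  # invariant under strictly monotone transforms of the pooled data
  set.seed(7)
  a <- rnorm(12); b <- rnorm(15, 1)
  h1 <- kruskal_wallis(a, b)$statistic
  h2 <- kruskal_wallis(exp(a), exp(b))$statistic
  expect_equal(h1, h2)
  # (values, groups) interface
  h3 <- kruskal_wallis(c(a, b), rep(c("a", "b"), c(12, 15)))$statistic
  expect_equal(h3, h1)
})

test_that("Tukey HSD on ranks separates what should be separated", {
  set.seed(8)
  same <- tukey_hsd_on_ranks(rnorm(15), rnorm(15))
  expect_true(all(same$p_adj > 0.05))
  # two far groups plus one overlapping the first
  g1 <- rnorm(15); g2 <- rnorm(15, 0.2); g3 <- rnorm(15, 30)
  tk <- tukey_hsd_on_ranks(list(g1 = g1, g2 = g2, g3 = g3))
  expect_gt(tk$p_adj[tk$pair == "g2-g1"], 0.05)
  expect_lt(tk$p_adj[tk$pair == "g3-g1"], 0.05)
  expect_lt(tk$p_adj[tk$pair == "g3-g2"], 0.05)
  # symmetric in group order (same adjusted p-values as a set)
  tk2 <- tukey_hsd_on_ranks(list(g3 = g3, g1 = g1, g2 = g2))
  expect_equal(sort(tk2$p_adj), sort(tk$p_adj))
  expect_warning(tukey_hsd_on_ranks(list(a = 1, b = rnorm(5), c = rnorm(5))),
                 "n = 1")
})

test_that("dispersion test measures spread, not location", {
  set.seed(9)
  # location-shift invariance: distances are centroid-relative
  x <- rnorm(60); g <- factor(rep(1:3, each = 20))
  shift <- c(0, 50, -30)[as.integer(g)]
  r1 <- dispersion_test(x, g, n_perm = 299, seed = 11)
  r2 <- dispersion_test(x + shift, g, n_perm = 299, seed = 11)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  # identical constants: p = 1 by convention
  const <- dispersion_test(rep(c(1, 2), each = 5),
                           factor(rep(c("a", "b"), each = 5)),
                           n_perm = 299, seed = 2)
  expect_equal(const$p_value, 1)
  # clear spread difference is detected
  y <- c(rnorm(20, 0, 1), rnorm(20, 0, 5))
  pow <- dispersion_test(y, factor(rep(1:2, each = 20)), n_perm = 499, seed = 3)
  expect_lt(pow$p_value, 0.05)
  # p bounded below by 1/(1+n_perm); reproducible under the seed
  expect_gte(pow$p_value, 1 / 500)
  pow2 <- dispersion_test(y, factor(rep(1:2, each = 20)), n_perm = 499, seed = 3)
  expect_equal(pow$p_value, pow2$p_value)
})

test_that("dispersion F statistic agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(10)
  x <- c(rnorm(15, 0, 1), rnorm(15, 0, 2), rnorm(15, 0, 4))
  g <- factor(rep(1:3, each = 15))
  ours <- dispersion_test(x, g, n_perm = 199, seed = 1)
  bd <- vegan::betadisper(dist(x), g, type = "centroid")
  f_vegan <- anova(bd)[1, "F value"]
  expect_equal(ours$statistic, f_vegan, tolerance = 1e-8)
})
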