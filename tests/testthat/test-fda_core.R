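test_that("the kernel smoother is a convex combination of the observations", {
  # constant and single-point limits
  expect_equal(nw_smooth(c(0, 30, 60), c(5, 5, 5), 7, seq(0, 60, 5)),
               rep(5, 13))
  expect_equal(nw_smooth(10, 3, 4, c(0, 50, 200)), rep(3, 3))
  # direct three-point evaluation
  t <- c(0, 30, 60); y <- c(1, 2, 4); h <- 15
  w <- dnorm((30 - t) / h)
  expect_equal(nw_smooth(t, y, h, 30), sum(w * y) / sum(w))
  # random trajectories stay within the observed range
  for (k in 1:20) {
    set.seed(k)
    n <- sample(3:9, 1)
    t <- sort(runif(n, 0, 150)); y <- rnorm(n)
    out <- nw_smooth(t, y, runif(1, 0.5, 200), seq(-10, 160, length.out = 40))
    expect_true(all(out >= min(y) - 1e-12 & out <= max(y) + 1e-12))
  }
  expect_error(nw_smooth(1:3, c(NA, NA, NA), 1, 1), "non-missing")
  expect_error(nw_smooth(1:3, 1:3, -1, 1), "positive")
})

test_that("GCV bandwidth selection matches an exhaustive scan and tie rules", {
  expect_equal(as.numeric(gcv_bandwidth(c(0, 30, 60), c(1, 2, 3), 7)), 7)
  # noiseless constant data: every GCV is 0, tie-break to the largest
  cand <- c(5, 10, 20, 40)
  expect_equal(as.numeric(gcv_bandwidth(seq(0, 150, 30), rep(2, 6), cand)), 40)
  # agrees with the independent exhaustive oracle
  for (k in 1:25) {
    set.seed(100 + k)
    t <- seq(0, 150, 30)
    y <- sin(t / 20) + rnorm(6, 0, 0.1)
    cand <- exp(seq(log(8), log(150), length.out = 20))
    expect_equal(as.numeric(gcv_bandwidth(t, y, cand)), oracle_gcv(t, y, cand))
  }
  expect_error(gcv_bandwidth(1:2, 1:2), "at least 3")
})

test_that("functional samples assemble on a common grid with a skip report", {
  df <- data.frame(
    individual_id = rep(c("a", "b", "c"), times = c(6, 6, 2)),
    t = c(seq(0, 150, 30), seq(0, 150, 30), c(0, 30)),
    y = c(rep(1, 6), rep(3, 6), c(9, 9)))
  expect_warning(fs <- build_functional_sample(df, "y", 21), "fewer than 3")
  expect_s3_class(fs, "functional_sample")
  expect_equal(dim(fs$curves), c(2L, 21L))
  expect_equal(fs$ids, c("a", "b"))
  expect_equal(fs$skipped$individual_id, "c")
  expect_equal(unname(fs$curves[1, ]), rep(1, 21))
  expect_equal(unname(fs$curves[2, ]), rep(3, 21))
  expect_equal(range(fs$grid), c(0, 150))
})

test_that("modal depth orders curves center-outward with stated invariances", {
  grid <- seq(0, 100, length.out = 11)
  flat <- function(c) rep(c, 11)
  fs <- functional_sample(grid, rbind(flat(0), flat(1), flat(10)))
  dep <- modal_depth(fs)
  expect_equal(unname(which.max(dep)), 2L)           # middle curve deepest
  expect_equal(unname(dep), oracle_modal_depth(fs$curves, grid))
  # identical curves: equal depths, no error
  fsI <- functional_sample(grid, rbind(flat(2), flat(2), flat(2)))
  expect_equal(diff(range(modal_depth(fsI))), 0)
  # translation invariance and order invariance under joint rescaling
  fsR <- gp_functional_sample(15, seed = 5)
  d0 <- modal_depth(fsR)
  shift <- sin(fsR$grid / 10)
  fsT <- functional_sample(fsR$grid, sweep(fsR$curves, 2, shift, "+"))
  expect_equal(unname(modal_depth(fsT)), unname(d0))
  fsS <- functional_sample(fsR$grid, 3.7 * fsR$curves)
  expect_equal(order(modal_depth(fsS)), order(d0))
})

test_that("depth outlier scan flags planted curves, not homogeneous ones", {
  # identical curves: nothing flagged
  grid <- seq(0, 100, length.out = 11)
  fsI <- functional_sample(grid, matrix(rep(1:11, each = 12), 12, byrow = FALSE))
  expect_length(trimmed_mode_outliers(fsI, seed = 1)$outlier_ids, 0)
  # planted +10 pooled-sd outlier is caught; flagged depths sit below cutoff
  hits <- 0L
  for (k in 1:10) {
    fs <- gp_functional_sample(20, seed = 400 + k)
    ps <- sd(as.numeric(fs$curves))
    fs$curves[7, ] <- fs$curves[7, ] + 10 * ps
    dr <- trimmed_mode_outliers(fs, B = 200, seed = 500 + k)
    hits <- hits + ("7" %in% dr$outlier_ids)
    if (nrow(dr$history) > 0)
      expect_true(all(dr$history$depth < dr$history$cutoff))
  }
  expect_gte(hits, 9L)
  # deterministic under a fixed seed
  fs <- gp_functional_sample(15, seed = 9)
  r1 <- trimmed_mode_outliers(fs, seed = 77)
  r2 <- trimmed_mode_outliers(fs, seed = 77)
  expect_identical(r1$depths, r2$depths)
  expect_identical(r1$outlier_ids, r2$outlier_ids)
  expect_error(trimmed_mode_outliers(gp_functional_sample(5, seed = 1), seed = 1),
               "at least 10")
})

test_that("bootstrap bands contain the mean and shrink with sample size", {
  grid <- seq(0, 100, length.out = 11)
  fsI <- functional_sample(grid, matrix(rep(1:11, each = 12), 12, byrow = FALSE))
  b <- bootstrap_band(fsI, B = 200, seed = 3)
  expect_equal(b$radius, 0)             # identical curves: band collapses
  expect_equal(b$lower, b$mean)
  fs10 <- gp_functional_sample(10, seed = 11)
  fs100 <- gp_functional_sample(100, seed = 12)
  b10 <- bootstrap_band(fs10, B = 300, seed = 4)
  b100 <- bootstrap_band(fs100, B = 300, seed = 5)
  expect_lt(b100$radius, b10$radius)    # ~ 1/sqrt(n)
  expect_true(all(b10$lower <= b10$mean & b10$mean <= b10$upper))
  expect_equal(functional_mean(fs10), colMeans(fs10$curves))
})

test_that("uniform band coverage of the true mean is close to nominal", {
  set.seed(21)
  hit <- replicate(150, {
    fs <- gp_functional_sample(50)
    b <- bootstrap_band(fs, B = 200, seed = sample.int(1e6, 1))
    all(b$lower <= 0 & 0 <= b$upper)    # generator has mean zero
  })
  expect_gt(mean(hit), 0.88)
  expect_lte(mean(hit), 1)
})
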