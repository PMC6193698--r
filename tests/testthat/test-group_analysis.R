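make_records <- function(first, final, var = "L") {
  n <- length(first)
  df <- data.frame(
    individual_id = rep(sprintf("m%02d", seq_len(n)), 2),
    t = rep(c(0, 150), each = n))
  df[[var]] <- c(first, final)
  df
}

test_that("even-start selection picks ids inside the target window", {
  rec <- make_records(c(20, 21, 21, 22), c(25, 30, 28, 33))
  expect_equal(select_even_start(rec, "L", 21, 0), c("m02", "m03"))
  expect_equal(select_even_start(rec, "L", 21, 5), sprintf("m%02d", 1:4))
  expect_error(select_even_start(rec, "L", 50, 0.1), "tolerance")
  # counting oracle on a rounded synthetic start distribution
  set.seed(12)
  L0 <- round(rnorm(200, 20.5, 0.5), 1)
  rec2 <- make_records(L0, L0 + 5)
  picked <- select_even_start(rec2, "L", 21, 0)
  expect_length(picked, sum(L0 == 21))
})

test_that("median split classifies growers and excludes exact ties", {
  gl <- classify_growers(make_records(rep(20, 4), c(1, 2, 3, 4)), "L")
  expect_equal(gl$label[order(gl$individual_id)][3:4], c("fast", "fast"))
  expect_equal(attr(gl, "cutpoint"), 2.5)
  expect_length(attr(gl, "excluded"), 0)

  expect_warning(
    gl2 <- suppressMessages(
      classify_growers(make_records(rep(20, 4), c(1, 2, 2, 3)), "L")),
    "single individual")
  expect_equal(sort(attr(gl2, "excluded")), c("m02", "m03"))
  expect_equal(sum(gl2$label == "fast"), 1)
  expect_equal(sum(gl2$label == "slow"), 1)
  # no individual is lost: fast + slow + excluded = input
  for (k in 1:10) {
    set.seed(200 + k)
    finals <- sample(1:8, 12, replace = TRUE)
    rec <- make_records(rep(20, 12), finals)
    gl3 <- tryCatch(suppressMessages(classify_growers(rec, "L")),
                    error = function(e) NULL)
    if (is.null(gl3)) next
    expect_setequal(c(gl3$individual_id, attr(gl3, "excluded")),
                    sprintf("m%02d", 1:12))
    expect_lte(abs(sum(gl3$label == "fast") - sum(gl3$label == "slow")),
               length(attr(gl3, "excluded")))
  }
})

test_that("functional ANOVA is exact at the degenerate point and reproducible", {
  grid <- seq(0, 100, length.out = 21)
  base <- gp_functional_sample(6, m = 21, seed = 31)$curves
  # both groups hold literally the same curve set: V = 0, p = 1
  fs <- functional_sample(grid, rbind(base, base))
  suppressWarnings(
    f0 <- fanova(fs, rep(c("a", "b"), each = 6), B = 199, seed = 1))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # non-negative statistic, deterministic under seed
  fs2 <- gp_functional_sample(20, seed = 32)
  lab <- rep(c("a", "b"), each = 10)
  fA <- fanova(fs2, lab, B = 300, seed = 5)
  fB <- fanova(fs2, lab, B = 300, seed = 5)
  expect_gte(fA$statistic, 0)
  expect_identical(fA$p_value, fB$p_value)
  # power grows with the planted shift
  ps <- sd(as.numeric(fs2$curves))
  p_at_shift <- sapply(c(0.5, 1, 2), function(s) {
    fss <- fs2
    fss$curves[11:20, ] <- fss$curves[11:20, ] + s * ps
    fanova(fss, lab, B = 300, seed = 6)$statistic
  })
  expect_true(all(diff(p_at_shift) > 0))
})

test_that("distance-covariance test sees identity and ignores joint reordering", {
  fsX <- gp_functional_sample(15, seed = 41)
  r <- functional_correlation_test(fsX, fsX, n_perm = 199, seed = 2)
  expect_equal(r$p_value, 1 / 200)
  # invariant to reordering individuals jointly
  perm <- sample(15)
  fsXp <- functional_sample(fsX$grid, fsX$curves[perm, ],
                            ids = fsX$ids[perm])
  fsY <- gp_functional_sample(15, seed = 42)
  fsYp <- functional_sample(fsY$grid, fsY$curves[perm, ],
                            ids = fsY$ids[perm])
  s1 <- functional_correlation_test(fsX, fsY, n_perm = 99, seed = 3)$statistic
  s2 <- functional_correlation_test(fsXp, fsYp, n_perm = 99, seed = 3)$statistic
  expect_equal(s1, s2)
  fsBad <- functional_sample(fsY$grid, fsY$curves, ids = rev(fsY$ids))
  expect_error(functional_correlation_test(fsX, fsBad, seed = 1),
               "same individuals")
})

test_that("group report covers every criterion-variable cell", {
  co <- generate_cohort(cohort_config(seed = 51))
  d <- derive_all(co$measurements, co$diet)
  ids <- select_even_start(d, "L", 21, 0.5)
  rep <- suppressMessages(
    compare_groups_report(d, ids = ids, grid_size = 31, B = 200,
                          B_band = 200, seed = 61))
  expect_equal(nrow(rep$table), 18L)     # 9 variables x 2 criteria
  expect_setequal(unique(rep$table$criterion), c("L", "TFW"))
  expect_setequal(unique(rep$table$variable),
                  c("L", "TFW", "SFG", "CR", "OIR", "AE", "AR", "VO2", "VNH4"))
  computed <- rep$table[rep$table$note == "", ]
  expect_true(all(computed$p_value >= 0 & computed$p_value <= 1))
  # planted quality effect shows up in the growth rows of the TFW split
  growth <- rep$table[rep$table$criterion == "TFW" &
                        rep$table$variable %in% c("L", "TFW"), ]
  expect_true(all(growth$p_value < 0.05))
  # band curves stored for computed cells
  expect_true(all(c("fast", "slow") %in% names(rep$curves$TFW$TFW)))
})
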