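test_that("agreement matches hand arithmetic and the published 2x2", {
  res <- agreement(concordance_table(8, 0, 0, 1))
  expect_identical(res$kappa, 1)
  expect_identical(res$sensitivity, 100)
  expect_identical(res$specificity, 100)
  expect_identical(res$kappa_band, "STRONG")

  expect_equal(agreement(concordance_table(5, 5, 5, 5))$kappa, 0)

  # hand-computed expected agreement for (45, 15, 25, 15)
  o <- oracle_agreement(45, 15, 25, 15)
  res2 <- agreement(concordance_table(45, 15, 25, 15))
  expect_equal(res2$kappa, o$kappa)
  expect_equal(res2$sensitivity, o$sensitivity)
  expect_equal(res2$specificity, o$specificity)
})

test_that("agreement matches brute force on all 2x2 tables with cells <= 6", {
  cells <- 0:6
  for (a in cells) for (b in cells) for (c_ in cells) for (d in cells) {
    if (a + b + c_ + d == 0) next
    got <- agreement(concordance_table(a, b, c_, d))
    want <- oracle_agreement(a, b, c_, d)
    expect_equal(got$kappa, want$kappa)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("kappa is 1 iff off-diagonal cells are zero (both classes present)", {
  set.seed(3)
  for (i in 1:50) {
    cells <- rpois(4, 4)
    if (cells[1] == 0 || cells[4] == 0) next  # need both classes present
    k <- agreement(do.call(concordance_table, as.list(cells)))$kappa
    expect_identical(isTRUE(all.equal(k, 1)),
                     cells[2] == 0 && cells[3] == 0)
  }
})

test_that("kappa bands follow the stated thresholds", {
  # (12,2,3,12): kappa = (24/29 - 420/841) / (1 - 420/841) ~ 0.655
  expect_identical(agreement(concordance_table(12, 2, 3, 12))$kappa_band,
                   "MODERATE")
  expect_identical(agreement(concordance_table(2, 6, 6, 2))$kappa_band,
                   "WEAK")
  # empty reference class is NA, never 0
  expect_true(is.na(agreement(concordance_table(0, 3, 0, 0))$sensitivity))
})

test_that("validation_concordance reproduces the published accounting", {
  # 11 loci, 1 discordant
  a <- sprintf("L%02d", 1:11)
  expect_identical(validation_concordance(a, a[-11], 11), 91)
  # 104 variants, 1 discordant, truncation convention
  b <- sprintf("V%03d", 1:104)
  expect_identical(
    validation_concordance(b, b[-104], 104, digits = 2,
                           convention = "truncate"),
    99.03)
  expect_identical(validation_concordance(a, a, 11), 100)
  expect_error(validation_concordance(a, a, 0), "positive")
  expect_error(validation_concordance(a, a, 5), "universe")
})

test_that("bland_altman computes limits of agreement with sample SD", {
  res <- bland_altman(c(50, 60, 40), c(40, 60, 50))
  expect_equal(res$mean_diff, 0)
  expect_equal(res$loa_high, 1.96 * 10)  # sd of {10, 0, -10} is 10
  expect_equal(res$loa_low, -1.96 * 10)

  same <- bland_altman(c(10, 20), c(10, 20))
  expect_identical(c(same$mean_diff, same$loa_low, same$loa_high), c(0, 0, 0))

  # LoA symmetry under negated differences
  set.seed(8)
  x <- runif(30, 0, 100); y <- x + rnorm(30, 1, 4)
  f <- bland_altman(x, y); g <- bland_altman(y, x)
  expect_equal(g$mean_diff, -f$mean_diff)
  expect_equal(g$loa_low, -f$loa_high)
  expect_equal(g$loa_high, -f$loa_low)

  # limits bracket ~95% of differences on large n by construction
  set.seed(9)
  xa <- runif(2000, 0, 100); xb <- xa + rnorm(2000, 0, 5)
  h <- bland_altman(xa, xb)
  inside <- mean(h$differences >= h$loa_low & h$differences <= h$loa_high)
  expect_gt(inside, 0.93)
  expect_error(bland_altman(1, numeric(0)))
})

test_that("linear_fit matches the closed-form normal equations", {
  f <- linear_fit(1:5, 2 * (1:5))
  expect_equal(f$slope, 2)
  expect_equal(f$pearson_r, 1)
  expect_equal(linear_fit(1:5, -(1:5))$pearson_r, -1)

  set.seed(4)
  x <- rnorm(40); y <- 3 + 1.7 * x + rnorm(40, 0, 0.5)
  f2 <- linear_fit(x, y)
  # brute-force normal equations
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(f2$slope, slope, tolerance = 1e-9)
  expect_equal(f2$intercept, mean(y) - slope * mean(x), tolerance = 1e-9)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})

test_that("rout_outliers flags gross outliers and leaves clean data alone", {
  expect_identical(rout_outliers(c(10, 11, 9, 10, 12, 10, 11)), integer(0))
  # oracle for the single-outlier case: exact t-tail on robust residuals
  vals <- c(10, 11, 9, 10, 12, 10, 1000)
  resid <- vals - median(vals)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * 7 / 6
  p_big <- 2 * pt(abs(resid[7]) / rsdr, df = 6, lower.tail = FALSE)
  expect_lt(p_big, 0.01 * 1 / 7)  # passes the most-extreme FDR slot
  expect_identical(rout_outliers(vals), 7L)

  expect_identical(rout_outliers(rep(5, 6)), integer(0))
  expect_error(rout_outliers(c(1, 2)), "at least 3")
  expect_error(rout_outliers(1:5, Q = 0))

  # Q -> 0 approaches no detections on clean Gaussian data
  set.seed(21)
  fp <- vapply(1:200, function(i) {
    length(rout_outliers(rnorm(44, 100, 10), Q = 0.01)) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.01)
})

test_that("coverage_stats computes depth, uniformity and read/depth ratio", {
  lens <- rep(100, 10)
  rec <- coverage_stats(list(S1 = rep(100, 10)), lens)
  expect_equal(rec$mean_depth, 100)
  expect_equal(rec$uniformity_pct, 100)
  expect_equal(rec$total_reads, 1000)

  # one amplicon at 10x with mean ~100x fails the 0.2x rule
  reads <- c(rep(110, 9), 10)
  rec2 <- coverage_stats(list(S1 = reads), lens)
  expect_lt(0.2 * rec2$mean_depth, 110)
  expect_gt(0.2 * rec2$mean_depth, 10)
  expect_equal(rec2$uniformity_pct, 90)

  expect_error(coverage_stats(list(S1 = 1:3), c(1, -1, 1)), "positive")
  expect_error(coverage_stats(list(S1 = 1:3), rep(1, 4)), "mismatch")

  # regression of total reads vs mean depth on a simulated cohort runs
  set.seed(12)
  pats <- lapply(1:20, function(i) rnbinom(50, mu = 500, size = 11))
  names(pats) <- sprintf("S%02d", 1:20)
  cov <- coverage_stats(pats, rep(150, 50))
  f <- linear_fit(cov$mean_depth, cov$total_reads)
  expect_gt(f$pearson_r, 0.999)  # ratio is constant by construction here
})
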