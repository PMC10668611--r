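test_that("residuals are automated minus manual", {
  p <- paired_measurements(x = c(5, 25), y = c(10, 20))
  expect_equal(ct_residuals(p), c(5, -5))
  expect_equal(ct_residuals(paired_measurements(1:4, 1:4)), rep(0, 4))
  expect_error(paired_measurements(1:3, 1:4), "equal length")
})

test_that("summary statistics behave on exact and shifted data", {
  x <- c(210, 250, 270, 300, 330, 360)
  s <- summary_stats(paired_measurements(x, x))
  expect_equal(s$mae_mean, 0)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$icc_3_1, 1)
  # consistency ICC ignores a fixed shift
  s2 <- summary_stats(paired_measurements(x, x + 12))
  expect_equal(s2$pearson_r, 1)
  expect_equal(s2$icc_3_1, 1, tolerance = 1e-12)
  expect_equal(s2$residual_mean, 12)
  expect_error(summary_stats(paired_measurements(rep(1, 5), 1:5)),
               "zero variance")
})

test_that("ICC(3,1) matches the two-way ANOVA mean-squares oracle", {
  x <- c(204, 233, 251, 269, 280, 312)
  y <- c(198, 241, 248, 275, 291, 305)
  # oracle: mean squares from stats::aov on the long two-way layout
  long <- data.frame(val = c(x, y),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(val ~ subj + rater, data = long))[[1]][
    , "Mean Sq"]
  bms <- ms[1]; ems <- ms[3]
  oracle <- (bms - ems) / (bms + (2 - 1) * ems)
  expect_equal(icc31(x, y), unname(oracle), tolerance = 1e-10)
  # equals Pearson on mean-centered, equal-variance pairs
  xm <- scale(x)[, 1]; ym <- scale(y)[, 1]
  expect_equal(icc31(xm, ym), cor(xm, ym), tolerance = 1e-12)
})

test_that("Passing-Bablok recovers exact linear relations", {
  set.seed(3)
  x <- sort(runif(10, 100, 400))
  pb1 <- passing_bablok(paired_measurements(x, x))
  expect_equal(pb1$slope, 1)
  expect_equal(pb1$intercept, 0)
  expect_true(pb1$slope_ci[1] <= 1 && pb1$slope_ci[2] >= 1)
  expect_true(pb1$intercept_ci[1] <= 0 && pb1$intercept_ci[2] >= 0)
  pb2 <- passing_bablok(paired_measurements(x, 2 * x + 3))
  expect_equal(pb2$slope, 2, tolerance = 1e-12)
  expect_equal(pb2$intercept, 3, tolerance = 1e-12)
})

test_that("Passing-Bablok slope equals the shifted-median enumeration", {
  set.seed(11)
  n <- 50
  x <- runif(n, 150, 450)
  y <- 1.05 * x - 8 + rnorm(n, 0, 15)
  pb <- passing_bablok(paired_measurements(x, y))
  # independent brute-force oracle
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- if (dx == 0) sign(dy) * Inf else dy / dx
    if (s != -1) slopes <- c(slopes, s)
  }
  slopes <- sort(slopes)
  N <- length(slopes); K <- sum(slopes < -1)
  oracle <- if (N %% 2 == 1) slopes[(N + 1) / 2 + K] else
    mean(slopes[N / 2 + K + 0:1])
  expect_identical(pb$slope, oracle)
  expect_identical(pb$intercept, median(y - oracle * x))
})

test_that("Passing-Bablok is scale-equivariant", {
  # exact equivariance requires that no pairwise slope crosses the
  # excluded value -1 under the transformation, so use monotone data
  set.seed(5)
  x <- seq(100, 500, length.out = 30)
  y <- 0.9 * x + 20 + rnorm(30, 0, 2)
  pb <- passing_bablok(paired_measurements(x, y))
  a <- 2.5; b <- -40
  pb2 <- passing_bablok(paired_measurements(x, a * y + b))
  expect_equal(pb2$slope, a * pb$slope, tolerance = 1e-9)
  expect_equal(pb2$intercept, a * pb$intercept + b, tolerance = 1e-9)
})

test_that("Bland-Altman limits follow mean +/- k SD", {
  ba0 <- bland_altman(rep(0, 5))
  expect_equal(ba0$mean, 0)
  expect_equal(ba0$loa, c(0, 0))
  ba <- bland_altman(c(-1, 0, 1))
  expect_equal(ba$mean, 0)
  expect_equal(ba$loa, c(-1.96, 1.96))
  set.seed(9)
  ban <- bland_altman(rnorm(1e5))
  expect_lt(max(abs(ban$loa - c(-1.96, 1.96))), 0.05)
})

test_that("major discrepancies use a strict 32-um rule", {
  fl <- flag_major(c(31.9, 32.0, 32.1))
  expect_equal(fl$flags, c(FALSE, FALSE, TRUE))
  expect_equal(flag_major(-50)$n_flagged, 1)
  # flag rate monotone non-increasing in the threshold
  set.seed(2)
  r <- rnorm(500, 0, 30)
  rates <- sapply(c(10, 20, 32, 50, 80),
                  function(th) flag_major(r, th)$fraction)
  expect_true(all(diff(rates) <= 0))
})

test_that("angular deviation series is unsigned and baseline-referenced", {
  ang <- data.frame(patient = rep("P1", 3), visit = c(0, 1, 2),
                    angle_deg = c(2, 5, -1))
  out <- angular_deviation_series(ang)
  expect_equal(out$deviations$deviation_deg, c(3, 3))
  # constant angles -> all-zero deviations
  angc <- data.frame(patient = rep(c("A", "B"), each = 3),
                     visit = rep(0:2, 2), angle_deg = 4)
  expect_true(all(angular_deviation_series(angc)$deviations$deviation_deg
                  == 0))
  # automated pathway: angle identically 0 -> deviations identically 0
  anga <- angc; anga$angle_deg <- 0
  expect_true(all(angular_deviation_series(anga)$per_visit$mean_deg == 0))
  # missing baseline errors
  bad <- data.frame(patient = c("A", "A", "B"), visit = c(0, 1, 1),
                    angle_deg = 1)
  expect_error(angular_deviation_series(bad), "baseline")
})

test_that("agreement_report bundles consistent numbers", {
  set.seed(21)
  manual <- runif(60, 150, 450)
  auto <- manual + rnorm(60, 2, 20)
  rep_ <- agreement_report(paired_measurements(manual, auto))
  res <- auto - manual
  expect_equal(rep_$residual_mean, mean(res))
  expect_equal(rep_$ba_mean, mean(res))
  expect_equal(rep_$n_flagged, sum(abs(res) > 32))
  expect_equal(rep_$flag_percent, 100 * mean(abs(res) > 32))
  expect_gt(rep_$icc_3_1, 0.9)
})
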