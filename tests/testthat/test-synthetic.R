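test_that("generate_bscan follows its curves and is deterministic", {
  p <- synth_scan_params(height_px = 256, width_px = 128,
                         rpe_curve = function(x) rep(100, length(x)),
                         cs_curve = function(x) rep(200, length(x)))
  g <- generate_bscan(p)
  expect_equal(dim(g$scan$pixels), c(256, 128))
  # flat curves 100 px apart: ground-truth separation 100 at every column
  expect_equal(g$truth$c_s$rows - g$truth$rpe_c$rows, rep(100, 128))
  # determinism: same params, same seed, bit-identical
  g2 <- generate_bscan(p)
  expect_identical(g$scan$pixels, g2$scan$pixels)
  # different seed with speckle differs
  p3 <- synth_scan_params(height_px = 256, width_px = 128,
                          rpe_curve = function(x) rep(100, length(x)),
                          cs_curve = function(x) rep(200, length(x)),
                          speckle_strength = 0.3, seed = 99)
  expect_false(identical(generate_bscan(p3)$scan$pixels, g$scan$pixels))
})

test_that("sinusoidal cs_curve amplitude is reproduced in the truth", {
  p <- synth_scan_params(
    height_px = 512, width_px = 256,
    rpe_curve = function(x) rep(150, length(x)),
    cs_curve = function(x) 300 + 30 * sin(2 * pi * (x - 1) / 255))
  g <- generate_bscan(p)
  # integer column sampling misses the analytic extrema by O(1/n^2)
  expect_equal(max(g$truth$c_s$rows) - min(g$truth$c_s$rows), 60,
               tolerance = 1e-3)
})

test_that("clean choroid band carries the configured intensity", {
  p <- synth_scan_params(height_px = 256, width_px = 64,
                         rpe_curve = function(x) rep(80, length(x)),
                         cs_curve = function(x) rep(180, length(x)))
  g <- generate_bscan(p)
  band <- g$scan$pixels[85:175, ]
  expect_equal(mean(band), 0.40, tolerance = 1 / 255)
})

test_that("curves leaving the image raise an invalid-parameter error", {
  p <- synth_scan_params(height_px = 128, width_px = 32,
                         rpe_curve = function(x) rep(100, length(x)),
                         cs_curve = function(x) rep(200, length(x)))
  expect_error(generate_bscan(p), "bounds")
  p2 <- synth_scan_params(height_px = 128, width_px = 32,
                          rpe_curve = function(x) rep(60, length(x)),
                          cs_curve = function(x) rep(50, length(x)))
  expect_error(generate_bscan(p2), "below")
})

test_that("zero-error grader reproduces perpendicular ground truth", {
  truth <- generate_bscan(synth_scan_params())$truth  # flat 100 px choroid
  g <- grader_params(angle_mean = 0, angle_sd = 0, landmark_jitter_sd = 0)
  cal <- simulate_manual_calipers(truth, g, c(-2000, 0, 2000))
  expect_true(all(cal$valid))
  expect_equal(cal$length_um, rep(100 * 3.87, 3), tolerance = 1e-6)
  expect_equal(cal$location_label, c("temporal", "subfoveal", "nasal"))
})

test_that("fixed-angle caliper length matches the secant closed form", {
  # flat choroid of exactly 300 um; fixed 10 degree angular error
  ax <- 3.87
  p <- synth_scan_params(rpe_curve = function(x) rep(300, length(x)),
                         cs_curve = function(x)
                           rep(300 + 300 / ax, length(x)))
  truth <- generate_bscan(p)$truth
  g <- grader_params(angle_mean = 10, angle_sd = 0, landmark_jitter_sd = 0)
  cal <- simulate_manual_calipers(truth, g, 0)
  # closed form: t / cos(theta); the package route is a numeric
  # line-polyline intersection
  expect_equal(cal$length_um, 300 / cos(10 * pi / 180), tolerance = 1e-6)
  expect_equal(cal$length_um, 304.63, tolerance = 1e-2)
})

test_that("angular error draws match their generating distribution", {
  truth <- generate_bscan(synth_scan_params())$truth
  g <- grader_params(angle_mean = 0.5, angle_sd = 2.5, seed = 42)
  cal <- simulate_manual_calipers(truth, g, rep(0, 1e4))
  expect_lt(abs(mean(cal$angle_deg) - 0.5), 0.1)
  expect_lt(abs(sd(cal$angle_deg) / 2.5 - 1), 0.05)
})

test_that("ground-truth thickness equals the analytic separation", {
  f_rpe <- function(x) 250 + 10 * cos(x / 40)
  f_cs <- function(x) 380 + 25 * sin(x / 60)
  p <- synth_scan_params(rpe_curve = f_rpe, cs_curve = f_cs)
  g <- generate_bscan(p)
  cols <- seq_len(768)
  expect_lt(max(abs((g$truth$c_s$rows - g$truth$rpe_c$rows) -
                    (f_cs(cols) - f_rpe(cols)))), 1e-6)
})

test_that("cohort generator is deterministic and respects zero noise", {
  p <- cohort_params(seed = 11)
  t1 <- generate_cohort(p)
  t2 <- generate_cohort(p)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), (9 + 9) * 6)
  # zero-noise construction: recipients' week-52 CT exactly +14.1%
  p0 <- cohort_params(noise_sd = 0, marker_re_sd = 0, auto_noise_sd = 0,
                      recipient_1yr_change = 0.141, seed = 2)
  t0 <- generate_cohort(p0)
  rec <- t0[t0$cohort == "recipient", ]
  base <- rec$true_ct[rec$visit_week == 0]
  yr <- rec$true_ct[rec$visit_week == 52]
  expect_equal(yr / base, rep(1.141, length(base)), tolerance = 1e-12)
})

test_that("markers are constant across visits when slopes and noise vanish", {
  p <- cohort_params(noise_sd = 0, marker_re_sd = 0, daytime_effect = 0,
                     recipient_1yr_change = 0, donor_1yr_change = 0,
                     patient_sd = 0,
                     choroid_marker_slopes = c(egfr = 0, creatinine = 0,
                                               urea = 0),
                     seed = 3)
  tab <- generate_cohort(p)
  for (m in c("egfr", "creatinine", "urea"))
    expect_equal(var(tab[[m]]), 0)
})

test_that("noise-free OLS on the cohort recovers the generating slopes", {
  p <- cohort_params(noise_sd = 0, marker_re_sd = 0, seed = 5)
  tab <- generate_cohort(p)
  tr <- attr(tab, "truth")
  for (m in c("egfr", "creatinine", "urea")) {
    y <- (tab[[m]] - tr$marker_location[[m]]) / tr$marker_scale[[m]]
    fit <- lm(y ~ tr$z_ct + tr$z_day)
    expect_equal(unname(coef(fit)[2]), unname(tr$latent_slopes[[m]]),
                 tolerance = 1e-10)
    expect_equal(unname(coef(fit)[3]), tr$daytime_effect, tolerance = 1e-10)
  }
})
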