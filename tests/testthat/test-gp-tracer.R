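test_that("gp_posterior returns the prior with no observations", {
  cfg <- gp_config(kernel_variance = 400)
  post <- gp_posterior(data.frame(column = integer(0), row = numeric(0)),
                       cfg, 1:10, prior_mean = 7)
  expect_equal(post$mean, rep(7, 10))
  expect_equal(post$sd, rep(20, 10))
})

test_that("gp_posterior interpolates a near-noiseless observation", {
  cfg <- gp_config(observation_noise_sd = 1e-4)
  post <- gp_posterior(data.frame(column = 5, row = 42), cfg, 5)
  expect_equal(post$mean, 42, tolerance = 1e-6)
  expect_lt(post$sd, 1e-3)
})

test_that("gp_posterior matches the closed-form dense oracle", {
  cfg <- gp_config(kernel_lengthscale = 30, kernel_variance = 100,
                   observation_noise_sd = 0.5)
  obs <- data.frame(column = c(3, 10, 21, 34, 55),
                    row = c(12, 14, 13.5, 17, 16))
  q <- c(1, 7, 15, 28, 44, 60)
  post <- gp_posterior(obs, cfg, q, lateral_scale = 2)
  oracle <- gp_oracle(obs$column, obs$row, q, lengthscale = 30,
                      variance = 100, noise_sd = 0.5, lateral_scale = 2)
  expect_equal(post$mean, oracle$mean, tolerance = 1e-8)
  expect_equal(post$sd, oracle$sd, tolerance = 1e-8)
})

test_that("duplicate observation columns raise a conditioning error", {
  cfg <- gp_config()
  expect_error(
    gp_posterior(data.frame(column = c(4, 4), row = c(1, 2)), cfg, 1:5),
    "singular|duplicate")
})

test_that("gradient KDE normalizes and localizes", {
  k <- kde_gradient_density(abs(c(-2, 2, -2, 2)) + rnorm(400, 0, 0.05))
  # density integrates to 1 and peaks near 2
  expect_equal(sum(k$y) * mean(diff(k$x)), 1, tolerance = 1e-3)
  expect_lt(abs(k$x[which.max(k$y)] - 2), 0.2)
  # standard-normal sample: density at 0 within 10% of 1/sqrt(2*pi)
  set.seed(7)
  kn <- kde_gradient_density(rnorm(1e4))
  expect_lt(abs(kde_density(kn, 0) / (1 / sqrt(2 * pi)) - 1), 0.1)
  # degenerate input falls back to a point mass with a warning
  expect_warning(kp <- kde_gradient_density(rep(3, 10)), "point mass")
  expect_equal(kde_weight(kp, c(2, 3, 4)), c(0, 1, 1))
})

test_that("candidate scoring is monotone in gradient and model density", {
  cfg <- gp_config(observation_noise_sd = 1, score_weight = 0.5)
  g <- matrix(0, 50, 3)
  kde <- kde_gradient_density(c(runif(100, 0.1, 1)))
  # equal gradients, different distance from the mean
  g[c(20, 28), 2] <- 0.5
  em <- edge_map_from_matrix(g)
  sc <- score_candidates(2, em, posterior_mean = 20, posterior_sd = 5,
                         config = cfg, kde = kde)
  expect_equal(sc$row[1], 20)  # at the mean scores highest
  # equidistant, different gradients
  g2 <- matrix(0, 50, 3)
  g2[16, 2] <- 0.9; g2[24, 2] <- 0.2
  sc2 <- score_candidates(2, edge_map_from_matrix(g2), 20, 5, cfg, kde)
  expect_equal(sc2$row[1], 16)
  # empty band
  sc3 <- score_candidates(1, em, 20, 5, cfg, kde)
  expect_equal(nrow(sc3), 0)
})

test_that("tracer recovers a noiseless straight edge within 1 px", {
  n <- 120
  g <- matrix(0, 100, n)
  rows <- round(seq(30, 60, length.out = n))
  g[cbind(rows, 1:n)] <- 1
  g <- g + matrix(runif(100 * n, 0, 1e-3), 100, n)  # KDE needs spread
  g[g < 1e-3 / 2] <- 0
  em <- edge_map_from_matrix(g)
  cfg <- gp_config(kernel_lengthscale = 30, batch_columns = 10)
  tr <- trace_boundary(em, rbind(c(1, rows[1]), c(n, rows[n])), cfg)
  expect_lte(max(abs(tr$rows - rows)), 1)
  # endpoints behave as data
  expect_lt(abs(tr$rows[1] - rows[1]), cfg$observation_noise_sd)
  expect_lt(abs(tr$rows[n] - rows[n]), cfg$observation_noise_sd)
  # determinism
  tr2 <- trace_boundary(em, rbind(c(1, rows[1]), c(n, rows[n])), cfg)
  expect_identical(tr$rows, tr2$rows)
})

test_that("tracer reaches generator ground truth under speckle", {
  p <- synth_scan_params(
    cs_curve = function(x) 420 + 30 * sin(2 * pi * (x - 1) / 767),
    speckle_strength = 0.3, seed = 7)
  g <- generate_bscan(p)
  em <- preprocess_bscan(g$scan, "c_s")
  truth <- g$truth$c_s$rows
  tr <- trace_boundary(em, rbind(c(1, truth[1]), c(768, truth[768])))
  expect_lte(mean(abs(tr$rows - truth)), 2)
})

test_that("occlusions inflate posterior SD but traces interpolate", {
  p <- synth_scan_params(
    cs_curve = function(x) 420 + 30 * sin(2 * pi * (x - 1) / 767),
    speckle_strength = 0.3, seed = 7)
  g <- generate_bscan(p)
  em <- preprocess_bscan(g$scan, "c_s")
  truth <- g$truth$c_s$rows
  ep <- rbind(c(1, truth[1]), c(768, truth[768]))
  tr_full <- trace_boundary(em, ep)
  # zero the edge map over a 300-um span (27 columns) mid-image
  gap <- 380:406
  em_gap <- em
  em_gap$gradient[, gap] <- 0
  tr_gap <- trace_boundary(em_gap, ep)
  # bounded deviation inside the gap
  expect_lte(max(abs(tr_gap$rows[gap] - tr_full$rows[gap])), 3)
  # uncertainty strictly higher inside the gap than outside; the first
  # columns of the gap sit next to accepted observations, so the strict
  # comparison applies to the gap interior
  outside <- setdiff(150:600, 370:416)
  interior <- 386:400
  expect_gt(min(tr_gap$sd[interior]), max(tr_gap$sd[outside]))
  expect_gt(mean(tr_gap$sd[gap]), mean(tr_gap$sd[outside]))
})

test_that("low-evidence inputs raise a diagnostic failure", {
  g <- matrix(0, 60, 80)
  g[30, c(1, 80)] <- 1
  g[25, 2:5] <- 0.5  # a little support near the left end only
  em <- edge_map_from_matrix(g)
  expect_error(trace_boundary(em, rbind(c(1, 30), c(80, 30))),
               "low-evidence")
})

test_that("two-boundary tracing keeps C-S below RPE-C", {
  p <- synth_scan_params(speckle_strength = 0.25, vessel_count = 5,
                         seed = 12)
  g <- generate_bscan(p)
  seg <- segment_choroid(
    g$scan,
    rpe_endpoints = rbind(c(1, g$truth$rpe_c$rows[1]),
                          c(768, g$truth$rpe_c$rows[768])),
    cs_endpoints = rbind(c(1, g$truth$c_s$rows[1]),
                         c(768, g$truth$c_s$rows[768])))
  span <- seg$span[1]:seg$span[2]
  expect_true(all(trace_row_at(seg$c_s, span) >
                  trace_row_at(seg$rpe_c, span)))
})
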