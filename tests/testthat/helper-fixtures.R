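# Fixtures built in code; no binary data.

# Segmentation from analytic curves, defaulting to Spectralis-like scales.
seg_from_curves <- function(rpe_rows, cs_rows, ncols = length(rpe_rows),
                            lateral_scale = 8700 / 768, axial_scale = 3.87,
                            fovea_column = ceiling(ncols / 2)) {
  cols <- seq_len(ncols)
  segmentation(boundary_trace(cols, rpe_rows),
               boundary_trace(cols, cs_rows),
               lateral_scale, axial_scale, fovea_column)
}

# Flat segmentation with given thickness (um), wide enough for the ETDRS
# window at default scales.
flat_seg <- function(thickness_um = 300, ncols = 768,
                     lateral_scale = 8700 / 768, axial_scale = 3.87,
                     rpe_row = 300) {
  seg_from_curves(rep(rpe_row, ncols),
                  rep(rpe_row + thickness_um / axial_scale, ncols),
                  lateral_scale = lateral_scale, axial_scale = axial_scale)
}

# Caliper at a given signed angle (deg) from vertical on a flat RPE-C,
# anchored at the fovea column of a segmentation.
angled_caliper <- function(seg, theta_deg, column = seg$fovea_column) {
  x <- (column - 1) * seg$lateral_scale
  y <- trace_row_at(seg$rpe_c, column) * seg$axial_scale
  dir <- c(sin(theta_deg * pi / 180), cos(theta_deg * pi / 180))
  list(anchor_x_um = x, anchor_y_um = y, dir_x = dir[1], dir_y = dir[2],
       location_label = "subfoveal")
}

trace_row_at <- choroidtrace:::trace_row_at

# Small edge map wrapper for tracer tests.
edge_map_from_matrix <- function(gradient, lateral_scale = 1,
                                 axial_scale = 1,
                                 polarity = "dark_to_bright") {
  structure(list(gradient = gradient, polarity = polarity,
                 lateral_scale = lateral_scale, axial_scale = axial_scale),
            class = "edge_map")
}

# Closed-form GP posterior oracle (textbook equations, dense solve()),
# independent of the package's Cholesky implementation.
gp_oracle <- function(obs_cols, obs_rows, query_cols, lengthscale, variance,
                      noise_sd, lateral_scale = 1) {
  k <- function(a, b) variance * exp(-outer(a, b, "-")^2 / (2 * lengthscale^2))
  xo <- (obs_cols - 1) * lateral_scale
  xq <- (query_cols - 1) * lateral_scale
  K <- k(xo, xo) + diag(noise_sd^2 + 1e-10, length(xo))
  Ki <- solve(K)
  Ks <- k(xq, xo)
  mean <- as.numeric(Ks %*% Ki %*% obs_rows)
  var <- pmax(variance - diag(Ks %*% Ki %*% t(Ks)), 0)
  list(mean = mean, sd = sqrt(var))
}
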