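# Gaussian-process edge tracing: each choroid boundary is modelled as a GP
# over lateral position (in micrometres) and grown by a recursive Bayesian
# scheme that scores candidate edge pixels by gradient evidence and
# posterior model density, accepting the best candidate per column.

#' Configuration of the Gaussian-process edge tracer
#'
#' @param kernel_lengthscale lateral lengthscale of the squared-exponential
#'   kernel, micrometres. Smooth anatomy motivates a physical lengthscale
#'   rather than a pixel one; 500 um spans ~44 columns at Spectralis
#'   resolution.
#' @param kernel_variance prior variance of the boundary row, pixels^2.
#' @param observation_noise_sd noise SD attached to accepted edge pixels,
#'   pixels. Also the floor of the candidate acceptance band: speckle
#'   mislocalizes gradient peaks by a few pixels, so values near 4 px
#'   (~15 um axially) keep the true edge inside the band while the
#'   posterior smooths the jitter out.
#' @param credible_multiplier half-width of the candidate acceptance band in
#'   posterior SDs (`>= 1`).
#' @param score_weight weight in `[0, 1]` of gradient evidence versus model
#'   density in the weighted geometric-mean score.
#' @param batch_columns columns advanced per recursion step from each end.
#' @param kde_bandwidth bandwidth rule or numeric value for the gradient
#'   kernel density estimate (passed to [stats::density]).
#' @return an object of class `gp_config`.
#' @export
gp_config <- function(kernel_lengthscale = 500, kernel_variance = 2500,
                      observation_noise_sd = 4, credible_multiplier = 3,
                      score_weight = 0.5, batch_columns = 15L,
                      kde_bandwidth = "nrd0") {
  check_scalar(kernel_lengthscale, "kernel_lengthscale", positive = TRUE)
  check_scalar(kernel_variance, "kernel_variance", positive = TRUE)
  check_scalar(observation_noise_sd, "observation_noise_sd", positive = TRUE)
  check_scalar(credible_multiplier, "credible_multiplier", positive = TRUE)
  if (credible_multiplier < 1)
    stop_invalid("credible_multiplier must be >= 1")
  if (score_weight < 0 || score_weight > 1)
    stop_invalid("score_weight must be in [0, 1]")
  check_scalar(batch_columns, "batch_columns", positive = TRUE,
               integerish = TRUE)
  structure(
    list(kernel_lengthscale = kernel_lengthscale,
         kernel_variance = kernel_variance,
         observation_noise_sd = observation_noise_sd,
         credible_multiplier = credible_multiplier,
         score_weight = score_weight,
         batch_columns = as.integer(batch_columns),
         kde_bandwidth = kde_bandwidth),
    class = "gp_config"
  )
}

sqexp_kernel <- function(x1, x2, variance, lengthscale) {
  d <- outer(x1, x2, "-")
  variance * exp(-d^2 / (2 * lengthscale^2))
}

#' Gaussian-process posterior over boundary row position
#'
#' Standard GP regression with a squared-exponential kernel over lateral
#' position measured in micrometres. With no observations the prior is
#' returned: `prior_mean` at every query and SD `sqrt(kernel_variance)`.
#'
#' @param observations data frame with columns `column` (distinct pixel
#'   column indices) and `row`; may have zero rows.
#' @param config a [gp_config].
#' @param query_columns column indices at which to evaluate the posterior.
#' @param lateral_scale micrometres per pixel used to place columns on the
#'   physical lateral axis.
#' @param prior_mean prior mean function of lateral position in um (or a
#'   constant); defaults to 0. The tracer passes the linear interpolant
#'   between the two endpoints.
#' @return list with `mean` and `sd` vectors over `query_columns`.
#' @export
gp_posterior <- function(observations, config, query_columns,
                         lateral_scale = 1, prior_mean = 0) {
  stopifnot(inherits(config, "gp_config"))
  mfun <- if (is.function(prior_mean)) prior_mean
          else function(x) rep(prior_mean, length(x))
  xq <- (query_columns - 1) * lateral_scale
  n <- if (is.null(observations)) 0L else nrow(observations)
  if (n == 0L) {
    return(list(mean = mfun(xq),
                sd = rep(sqrt(config$kernel_variance), length(xq))))
  }
  if (anyDuplicated(observations$column))
    stop_invalid("duplicate observation columns give a singular covariance")
  xo <- (observations$column - 1) * lateral_scale
  yo <- observations$row
  K <- sqexp_kernel(xo, xo, config$kernel_variance,
                    config$kernel_lengthscale)
  diag(K) <- diag(K) + config$observation_noise_sd^2 + 1e-10
  L <- tryCatch(chol(K), error = function(e)
    stop_invalid("singular GP covariance (ill-conditioned observations): ",
                 conditionMessage(e)))
  Ks <- sqexp_kernel(xq, xo, config$kernel_variance,
                     config$kernel_lengthscale)
  alpha <- backsolve(L, forwardsolve(t(L), yo - mfun(xo)))
  mean_q <- mfun(xq) + as.numeric(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))
  var_q <- pmax(config$kernel_variance - colSums(V^2), 0)
  list(mean = mean_q, sd = sqrt(var_q))
}

#' Kernel density estimate of gradient magnitudes
#'
#' Gaussian-kernel density over the nonzero gradient magnitudes of an edge
#' map. The tracer uses the associated cumulative distribution as a
#' monotone relative evidence weight: pixels with gradients in the upper
#' tail of the image's gradient distribution carry weight near 1.
#'
#' @param gradient_values numeric vector (at least 2 finite values).
#' @param bandwidth bandwidth rule or value for [stats::density].
#' @return an object of class `gradient_kde`: callable as a density via
#'   `predict`-style helpers `kde_density(obj, x)` and `kde_weight(obj, x)`
#'   (the CDF). Degenerate all-identical input falls back to a point mass
#'   with a warning.
#' @export
kde_gradient_density <- function(gradient_values, bandwidth = "nrd0") {
  v <- gradient_values[is.finite(gradient_values)]
  if (length(v) < 2L) stop_invalid("need at least 2 finite gradient values")
  if (sd(v) == 0) {
    warning("degenerate bandwidth (all gradient values identical); ",
            "falling back to a point mass", call. = FALSE)
    return(structure(list(point_mass = v[1]), class = "gradient_kde"))
  }
  d <- density(v, bw = bandwidth, n = 512)
  cdf <- cumsum(d$y) * mean(diff(d$x))
  cdf <- cdf / max(cdf)
  structure(
    list(x = d$x, y = d$y, cdf = cdf, bw = d$bw),
    class = "gradient_kde"
  )
}

#' @rdname kde_gradient_density
#' @param obj a `gradient_kde`.
#' @param x evaluation points.
#' @export
kde_density <- function(obj, x) {
  if (!is.null(obj$point_mass)) return(ifelse(x == obj$point_mass, Inf, 0))
  approx(obj$x, obj$y, xout = x, yleft = 0, yright = 0)$y
}

#' @rdname kde_gradient_density
#' @export
kde_weight <- function(obj, x) {
  if (!is.null(obj$point_mass)) return(as.numeric(x >= obj$point_mass))
  approx(obj$x, obj$cdf, xout = x, yleft = 0, yright = 1)$y
}

#' Score candidate edge pixels in one column
#'
#' Candidates are the rows with nonzero edge-map support inside the
#' credible band `posterior_mean +/- credible_multiplier * posterior_sd`.
#' Each is scored by a weighted geometric mean of its gradient evidence
#' weight (KDE cumulative weight) and the Gaussian posterior model density
#' at its row (normalized to 1 at the posterior mean), so the score is zero
#' whenever either evidence term vanishes.
#'
#' @param column pixel column index.
#' @param edge_map an `edge_map` from [build_edge_map].
#' @param posterior_mean,posterior_sd posterior row mean and SD at `column`.
#' @param config a [gp_config].
#' @param kde a `gradient_kde` over the edge map's nonzero gradients; built
#'   on the fly when `NULL`.
#' @return data frame `(row, score)`, possibly empty, sorted by decreasing
#'   score with deterministic tie-breaking (closer to the posterior mean,
#'   then smaller row).
#' @export
score_candidates <- function(column, edge_map, posterior_mean, posterior_sd,
                             config, kde = NULL) {
  stopifnot(inherits(edge_map, "edge_map"))
  if (posterior_sd < 0) stop_invalid("posterior_sd must be >= 0")
  g <- edge_map$gradient[, column]
  nr <- length(g)
  band_sd <- max(posterior_sd, config$observation_noise_sd)
  lo <- max(1L, floor(posterior_mean - config$credible_multiplier * band_sd))
  hi <- min(nr, ceiling(posterior_mean + config$credible_multiplier * band_sd))
  if (lo > hi) return(data.frame(row = integer(0), score = numeric(0)))
  rows <- lo:hi
  rows <- rows[g[rows] > 0]
  if (length(rows) == 0L)
    return(data.frame(row = integer(0), score = numeric(0)))
  if (is.null(kde))
    kde <- kde_gradient_density(edge_map$gradient[edge_map$gradient > 0],
                                config$kde_bandwidth)
  w_grad <- kde_weight(kde, g[rows])
  dens <- exp(-(rows - posterior_mean)^2 / (2 * band_sd^2))
  score <- w_grad^config$score_weight * dens^(1 - config$score_weight)
  ord <- order(-score, abs(rows - posterior_mean), rows)
  data.frame(row = rows[ord], score = score[ord])
}

#' Trace one boundary by recursive Bayesian GP edge growing
#'
#' The two manually supplied endpoints enter as the initial observations
#' and define a linear-interpolant prior mean. The scheme then repeatedly
#' (a) fits the GP posterior to the accepted observations, (b) scores
#' candidates on the next `batch_columns` unvisited columns advancing
#' symmetrically inward from both endpoints, (c) accepts the best-scoring
#' candidate per column (columns without support are skipped and later
#' covered by posterior interpolation), and (d) refits, until every column
#' in the span has been visited. The returned trace is the final posterior
#' evaluated on every column of the span, so occluded regions carry
#' inflated posterior SD rather than spurious observations.
#'
#' @param edge_map an `edge_map`.
#' @param endpoints two-row matrix or list of two `c(col, row)` pairs; the
#'   left endpoint column must precede the right one.
#' @param config a [gp_config].
#' @return a [boundary_trace] over the endpoint-to-endpoint span.
#' @export
trace_boundary <- function(edge_map, endpoints, config = gp_config()) {
  stopifnot(inherits(edge_map, "edge_map"))
  if (is.list(endpoints)) endpoints <- do.call(rbind, endpoints)
  endpoints <- matrix(as.numeric(endpoints), ncol = 2)
  if (nrow(endpoints) < 2L) stop_invalid("two endpoints are required")
  if (endpoints[1, 1] >= endpoints[2, 1])
    stop_invalid("left endpoint column must precede the right endpoint")
  nr <- nrow(edge_map$gradient); nc <- ncol(edge_map$gradient)
  if (any(endpoints[, 1] < 1 | endpoints[, 1] > nc |
          endpoints[, 2] < 1 | endpoints[, 2] > nr))
    stop_invalid("endpoints outside the image")
  lat <- edge_map$lateral_scale
  ep_x <- (endpoints[, 1] - 1) * lat
  prior_mean <- function(x) linear_interp(ep_x, endpoints[, 2], x)
  obs <- data.frame(column = as.integer(round(endpoints[, 1])),
                    row = endpoints[, 2])
  span <- obs$column[1]:obs$column[2]
  interior <- setdiff(span, obs$column)
  pos_grad <- edge_map$gradient[edge_map$gradient > 0]
  kde <- if (length(pos_grad) >= 2)
    kde_gradient_density(pos_grad, config$kde_bandwidth) else NULL
  left <- obs$column[1]; right <- obs$column[2]
  n_missed <- 0L
  while (left + 1 <= right - 1) {
    take_l <- intersect((left + 1):min(left + config$batch_columns, right - 1),
                        interior)
    remaining_lo <- if (length(take_l)) max(take_l) + 1 else left + 1
    lo_r <- max(remaining_lo, right - config$batch_columns)
    take_r <- if (lo_r > right - 1) integer(0)
              else intersect(lo_r:(right - 1), interior)
    batch <- sort(unique(c(take_l, take_r)))
    if (length(batch) == 0L) break
    post <- gp_posterior(obs, config, batch, lat, prior_mean)
    for (i in seq_along(batch)) {
      cand <- score_candidates(batch[i], edge_map, post$mean[i], post$sd[i],
                               config, kde)
      if (nrow(cand) == 0L || cand$score[1] <= 0) {
        n_missed <- n_missed + 1L
      } else {
        obs <- rbind(obs,
                     data.frame(column = batch[i], row = cand$row[1]))
      }
    }
    left <- if (length(take_l)) max(take_l) else left
    right <- if (length(take_r)) min(take_r) else right
    if (length(take_l) == 0L && length(take_r) == 0L) break
  }
  if (n_missed > 0.5 * max(length(interior), 1L))
    stop_invalid(sprintf(
      "low-evidence failure: %d of %d columns had no candidate edge pixel",
      n_missed, length(interior)))
  post <- gp_posterior(obs[order(obs$column), ], config, span, lat,
                       prior_mean)
  boundary_trace(span, pmin(pmax(post$mean, 1), nr), post$sd,
                 accepted_observations = obs[order(obs$column), ])
}

#' Convenience endpoint heuristic (extension, not part of the core method)
#'
#' The tracing method expects manually selected endpoint pixels. This
#' heuristic, provided purely as a convenience for scripted runs, picks the
#' strongest edge response in the first and last image columns that still
#' have support.
#'
#' @param edge_map an `edge_map`.
#' @return 2 x 2 matrix of `(col, row)` endpoints.
#' @export
suggest_endpoints <- function(edge_map) {
  g <- edge_map$gradient
  nz <- which(colSums(g) > 0)
  if (length(nz) < 2L) stop_invalid("no edge support to pick endpoints from")
  c1 <- min(nz); c2 <- max(nz)
  rbind(c(c1, which.max(g[, c1])), c(c2, which.max(g[, c2])))
}

#' Segment both choroid boundaries of a B-scan
#'
#' Runs the preprocessing pipeline per boundary (bright-to-dark polarity
#' for RPE-C, dark-to-bright for C-S), traces each with the GP scheme, and
#' checks the two-boundary consistency (C-S strictly below RPE-C).
#'
#' @param scan a [bscan].
#' @param rpe_endpoints,cs_endpoints endpoint pairs for the two boundaries.
#' @param config a [gp_config].
#' @param ... preprocessing parameters passed to [preprocess_bscan].
#' @return a [segmentation].
#' @export
segment_choroid <- function(scan, rpe_endpoints, cs_endpoints,
                            config = gp_config(), median_window = 5L,
                            clip_limit = 0.005, tiles = c(8L, 8L), ...) {
  # denoise + contrast-enhance once; only the derivative polarity differs
  # between the two boundaries
  pre <- enhance_clahe(denoise_median(scan, median_window), clip_limit,
                       tiles)
  em_rpe <- build_edge_map(pre, "bright_to_dark", ...)
  em_cs <- build_edge_map(pre, "dark_to_bright", ...)
  rpe <- trace_boundary(em_rpe, rpe_endpoints, config)
  cs <- trace_boundary(em_cs, cs_endpoints, config)
  segmentation(rpe, cs, scan$lateral_scale, scan$axial_scale,
               scan$fovea_column)
}
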