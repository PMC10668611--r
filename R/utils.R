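# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_invalid(name, " must be a whole number")
  invisible(x)
}

# Nearest integer with exact .5 ties rounded toward zero. Used for column
# snapping so a +2000 um offset and a -2000 um offset snap symmetrically
# toward the fovea.
round_half_toward_zero <- function(x) {
  sign(x) * ceiling(abs(x) - 0.5)
}

# First intersection of the ray anchor + t * dir (t > 0) with the piecewise
# linear curve (xs, ys). All coordinates in the same (physical) units.
# Returns the ray parameter t (= distance when dir is unit) or NA.
ray_polyline_intersection <- function(anchor, dir, xs, ys) {
  n <- length(xs)
  if (n < 2L) return(NA_real_)
  sx <- xs[-n]; sy <- ys[-n]
  ex <- xs[-1L]; ey <- ys[-1L]
  gx <- ex - sx; gy <- ey - sy
  # Solve anchor + t*dir = seg_start + s*seg_dir for each segment.
  det <- dir[1] * (-gy) - dir[2] * (-gx)
  rhs_x <- sx - anchor[1]
  rhs_y <- sy - anchor[2]
  ok <- abs(det) > 1e-12
  t_par <- rep(NA_real_, n - 1L)
  s_par <- rep(NA_real_, n - 1L)
  t_par[ok] <- (rhs_x[ok] * (-gy[ok]) - rhs_y[ok] * (-gx[ok])) / det[ok]
  s_par[ok] <- (dir[1] * rhs_y[ok] - dir[2] * rhs_x[ok]) / det[ok]
  hit <- ok & t_par > 1e-9 & s_par >= -1e-9 & s_par <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  min(t_par[hit])
}

# Tangent slope (dy/dx) of a sampled curve at position x0, estimated by a
# least-squares line over points within +/- window of x0 (same units as x).
local_tangent_slope <- function(xs, ys, x0, window) {
  keep <- abs(xs - x0) <= window + 1e-9
  if (sum(keep) < 2L) {
    # fall back to the two nearest points
    ord <- order(abs(xs - x0))[1:2]
    keep <- seq_along(xs) %in% ord
  }
  xk <- xs[keep]; yk <- ys[keep]
  xc <- xk - mean(xk)
  denom <- sum(xc^2)
  if (denom < 1e-12) return(0)
  sum(xc * (yk - mean(yk))) / denom
}

# Inward (downward, toward larger row/y) unit normal of a curve with local
# tangent slope m, in physical coordinates where y grows downward.
inward_normal <- function(slope) {
  tangent <- c(1, slope) / sqrt(1 + slope^2)
  nrm <- c(-tangent[2], tangent[1])
  if (nrm[2] < 0) nrm <- -nrm
  nrm
}

# Rotate a vector by theta degrees in image coordinates (y grows downward).
# Positive theta tilts a downward-pointing vector toward +x (nasal for a
# right eye), matching the signed-angle convention of measurement_angle().
rotate_deg <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] + sin(th) * v[2],
    -sin(th) * v[1] + cos(th) * v[2])
}

linear_interp <- function(x, y, xout) {
  approx(x, y, xout = xout, rule = 2)$y
}
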