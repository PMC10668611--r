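# Fovea-referenced choroid measurement in physical units: perpendicular and
# parallel thickness at named macular locations, area over the ETDRS window.

seg_um_curves <- function(seg) {
  span <- seg$span[1]:seg$span[2]
  list(
    x = (span - 1) * seg$lateral_scale,
    rpe = trace_row_at(seg$rpe_c, span) * seg$axial_scale,
    cs = trace_row_at(seg$c_s, span) * seg$axial_scale,
    fovea_x = (seg$fovea_column - 1) * seg$lateral_scale,
    span = span
  )
}

ct_measure <- function(location_label, mode, thickness_um, angle_deg,
                       column) {
  structure(
    list(location_label = location_label, mode = mode,
         thickness_um = thickness_um, angle_deg = angle_deg,
         column = column),
    class = "ct_measure"
  )
}

#' @export
print.ct_measure <- function(x, ...) {
  cat(sprintf("<ct_measure> %s %s: %.1f um (angle %.2f deg, col %d)\n",
              x$location_label, x$mode, x$thickness_um, x$angle_deg,
              x$column))
  invisible(x)
}

#' Fovea-referenced measurement columns
#'
#' Converts micrometre offsets from the fovea to pixel columns (nearest
#' integer, exact ties snapped toward the fovea) and labels them
#' temporal / subfoveal / nasal according to eye laterality. The standard
#' macular protocol measures at the fovea and 2000 um temporal and nasal.
#'
#' @param seg a [segmentation].
#' @param offsets_um lateral offsets in micrometres (negative = temporal
#'   for a right eye).
#' @return data frame `(label, offset_um, column)`.
#' @export
reference_columns <- function(seg, offsets_um = c(-2000, 0, 2000)) {
  stopifnot(inherits(seg, "segmentation"))
  cols <- seg$fovea_column +
    round_half_toward_zero(offsets_um / seg$lateral_scale)
  if (any(cols < seg$span[1] | cols > seg$span[2]))
    stop_invalid("offset outside the trace span")
  data.frame(
    label = vapply(offsets_um, location_label, "", eye = seg$eye),
    offset_um = offsets_um,
    column = as.integer(cols),
    stringsAsFactors = FALSE
  )
}

#' Perpendicular choroidal thickness at a column
#'
#' Works in micrometre space. The RPE-C tangent at the column is estimated
#' by a least-squares line over columns within `tangent_window_um`; a ray
#' is cast from the RPE-C point along the inward normal and the thickness
#' is the distance to its intersection with the piecewise-linear C-S curve.
#'
#' @param seg a [segmentation].
#' @param column pixel column inside the trace span.
#' @param tangent_window_um half-width of the tangent-estimation window in
#'   micrometres.
#' @return a `ct_measure` with `mode = "perpendicular"` and angle 0.
#' @export
perpendicular_ct <- function(seg, column, tangent_window_um = 50) {
  stopifnot(inherits(seg, "segmentation"))
  cu <- seg_um_curves(seg)
  if (column < seg$span[1] || column > seg$span[2])
    stop_invalid("column outside the trace span")
  x0 <- (column - 1) * seg$lateral_scale
  anchor <- c(x0, linear_interp(cu$x, cu$rpe, x0))
  slope <- local_tangent_slope(cu$x, cu$rpe, x0, tangent_window_um)
  dir <- inward_normal(slope)
  len <- ray_polyline_intersection(anchor, dir, cu$x, cu$cs)
  if (is.na(len))
    stop_invalid("perpendicular ray exits the span before meeting C-S")
  ct_measure(label_for_column(seg, column), "perpendicular", len, 0,
             as.integer(column))
}

label_for_column <- function(seg, column) {
  off <- (column - seg$fovea_column) * seg$lateral_scale
  if (abs(off) < seg$lateral_scale / 2) return("subfoveal")
  location_label(off, seg$eye)
}

#' Parallel choroidal thickness along a caliper direction
#'
#' Mimics a manual caliper: casts a ray from the caliper anchor along the
#' caliper direction and measures the distance to the C-S intersection,
#' recording the signed angle from the local perpendicular.
#'
#' @param seg a [segmentation].
#' @param caliper one row of a caliper data frame as produced by
#'   [simulate_manual_calipers] (fields `anchor_x_um`, `anchor_y_um`,
#'   `dir_x`, `dir_y`, `location_label`), or a list with those fields.
#' @param tangent_window_um window for the local-normal estimate.
#' @return a `ct_measure` with `mode = "parallel"`.
#' @export
parallel_ct <- function(seg, caliper, tangent_window_um = 50) {
  stopifnot(inherits(seg, "segmentation"))
  cu <- seg_um_curves(seg)
  anchor <- c(caliper$anchor_x_um, caliper$anchor_y_um)
  rpe_y <- linear_interp(cu$x, cu$rpe, anchor[1])
  if (abs(anchor[2] - rpe_y) > seg$axial_scale + 1e-6)
    stop_invalid("caliper anchor is more than 1 px from the RPE-C trace")
  dir <- c(caliper$dir_x, caliper$dir_y)
  dir <- dir / sqrt(sum(dir^2))
  len <- ray_polyline_intersection(anchor, dir, cu$x, cu$cs)
  if (is.na(len))
    stop_invalid("caliper ray exits the span before meeting C-S")
  ang <- measurement_angle(caliper, seg, tangent_window_um)
  col <- as.integer(round(anchor[1] / seg$lateral_scale + 1))
  ct_measure(caliper$location_label %||% label_for_column(seg, col),
             "parallel", len, ang, col)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed angle between a caliper and the local perpendicular
#'
#' Computed in micrometre space so the anisotropic pixel scales do not
#' distort the angle. Positive angles are rotations of the inward normal
#' toward the nasal side (+x for a right eye).
#'
#' @inheritParams parallel_ct
#' @return signed angle in degrees.
#' @export
measurement_angle <- function(caliper, seg, tangent_window_um = 50) {
  stopifnot(inherits(seg, "segmentation"))
  cu <- seg_um_curves(seg)
  dir <- c(caliper$dir_x, caliper$dir_y)
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-12) stop_invalid("zero-length caliper")
  dir <- dir / nd
  slope <- local_tangent_slope(cu$x, cu$rpe, caliper$anchor_x_um,
                               tangent_window_um)
  n <- inward_normal(slope)
  atan2(dir[1] * n[2] - dir[2] * n[1], sum(dir * n)) * 180 / pi
}

#' Choroidal area over the ETDRS window
#'
#' Trapezoidal integral of the vertical RPE-C to C-S separation (in um)
#' over lateral micrometres across `|x - fovea| <= half_width_um`,
#' returned in square millimetres. The "3000-micron radius" of the macular
#' protocol is interpreted as a lateral half-width (a vertical strip of
#' the 6000 x 6000 um ETDRS square on a single B-scan).
#'
#' @param seg a [segmentation].
#' @param half_width_um lateral half-width, default 3000.
#' @return list of class `ca_measure`: `area_mm2`, `half_width_um`,
#'   `fovea_column`.
#' @export
choroid_area <- function(seg, half_width_um = 3000) {
  stopifnot(inherits(seg, "segmentation"))
  check_scalar(half_width_um, "half_width_um", positive = TRUE)
  cu <- seg_um_curves(seg)
  x_lo <- cu$fovea_x - half_width_um
  x_hi <- cu$fovea_x + half_width_um
  if (x_lo < min(cu$x) - 1e-9 || x_hi > max(cu$x) + 1e-9)
    stop_invalid("ETDRS window extends beyond the trace span")
  thick <- cu$cs - cu$rpe
  inside <- cu$x > x_lo & cu$x < x_hi
  xs <- c(x_lo, cu$x[inside], x_hi)
  ts <- c(linear_interp(cu$x, thick, x_lo), thick[inside],
          linear_interp(cu$x, thick, x_hi))
  area_um2 <- sum(diff(xs) * (head(ts, -1) + ts[-1]) / 2)
  structure(
    list(area_mm2 = area_um2 / 1e6, half_width_um = half_width_um,
         fovea_column = seg$fovea_column),
    class = "ca_measure"
  )
}

#' @export
print.ca_measure <- function(x, ...) {
  cat(sprintf("<ca_measure> %.4f mm2 over +/-%.0f um\n",
              x$area_mm2, x$half_width_um))
  invisible(x)
}

#' Average choroidal thickness across macular locations
#'
#' Collapses the per-location measurements of one scan to a single CT value
#' (arithmetic mean), the summary used for longitudinal analysis.
#'
#' @param measures list of `ct_measure` objects (or numeric thicknesses).
#' @return mean thickness in micrometres.
#' @export
average_ct <- function(measures) {
  if (length(measures) == 0L) stop_invalid("no measurements to average")
  vals <- vapply(measures, function(m)
    if (inherits(m, "ct_measure")) m$thickness_um else as.numeric(m),
    numeric(1))
  mean(vals)
}

#' Measure a segmented scan at the standard macular locations
#'
#' @param seg a [segmentation].
#' @param offsets_um lateral measurement offsets.
#' @param half_width_um ETDRS half-width for the area measure.
#' @return list with `ct` (data frame of perpendicular measurements),
#'   `average_ct_um` and `area_mm2`.
#' @export
measure_scan <- function(seg, offsets_um = c(-2000, 0, 2000),
                         half_width_um = 3000) {
  refs <- reference_columns(seg, offsets_um)
  ms <- lapply(refs$column, function(col) perpendicular_ct(seg, col))
  ct <- data.frame(
    label = refs$label, offset_um = refs$offset_um, column = refs$column,
    thickness_um = vapply(ms, `[[`, numeric(1), "thickness_um"),
    stringsAsFactors = FALSE
  )
  list(ct = ct, average_ct_um = average_ct(ms),
       area_mm2 = choroid_area(seg, half_width_um)$area_mm2)
}
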