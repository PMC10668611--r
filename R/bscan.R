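#' Construct a B-scan object
#'
#' A B-scan is a single cross-sectional OCT image: a matrix of gray
#' intensities in `[0, 1]` with rows running axially (row 1 = top of the
#' image, i.e. the vitreous) and columns laterally, plus the physical pixel
#' scales and the fovea reference column needed to convert measurements to
#' micrometres. Columns increase temporal-to-nasal for a right eye.
#'
#' @param pixels numeric matrix of intensities; values are normalized to
#'   `[0, 1]` if the input range exceeds 1 (e.g. 8-bit data).
#' @param lateral_scale,axial_scale micrometres per pixel, both `> 0`.
#' @param fovea_column column index (1-based) of the foveal pit.
#' @param meta named list of acquisition metadata (decimal-hour daytime,
#'   scan focus in diopters, patient/visit identifiers, ...).
#' @return an object of class `bscan`.
#' @export
bscan <- function(pixels, lateral_scale, axial_scale, fovea_column,
                  meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_invalid("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_invalid("pixel intensities must be finite")
  check_scalar(lateral_scale, "lateral_scale", positive = TRUE)
  check_scalar(axial_scale, "axial_scale", positive = TRUE)
  check_scalar(fovea_column, "fovea_column", integerish = TRUE)
  if (fovea_column < 1 || fovea_column > ncol(pixels))
    stop_invalid("fovea_column outside image width")
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / mx
  if (min(pixels) < 0) stop_invalid("pixel intensities must be >= 0")
  structure(
    list(pixels = pixels, lateral_scale = lateral_scale,
         axial_scale = axial_scale, fovea_column = as.integer(fovea_column),
         meta = meta),
    class = "bscan"
  )
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' @export
print.bscan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<bscan> %d x %d px | %.2f um/px lateral, %.2f um/px axial | fovea col %d\n",
    d[1], d[2], x$lateral_scale, x$axial_scale, x$fovea_column))
  invisible(x)
}

# replace the pixel grid, keeping scales and metadata
update_pixels <- function(scan, pixels) {
  scan$pixels <- pixels
  scan
}

#' Construct a boundary trace
#'
#' A sub-pixel column-to-row curve describing one traced junction (RPE-C or
#' C-S), with a per-column posterior standard deviation when produced by the
#' Gaussian-process tracer (zero for ground truth).
#'
#' @param columns strictly increasing integer column indices.
#' @param rows sub-pixel row positions (posterior mean), one per column.
#' @param sd per-column standard deviation in pixels (default 0).
#' @param accepted_observations optional data frame `(column, row)` of edge
#'   pixels accepted as observations by the tracer.
#' @return an object of class `boundary_trace`.
#' @export
boundary_trace <- function(columns, rows, sd = 0,
                           accepted_observations = NULL) {
  columns <- as.integer(columns)
  if (length(columns) != length(rows))
    stop_invalid("columns and rows must have equal length")
  if (any(diff(columns) <= 0))
    stop_invalid("columns must be strictly increasing")
  if (any(!is.finite(rows))) stop_invalid("rows must be finite")
  sd <- rep_len(sd, length(columns))
  if (any(sd < 0)) stop_invalid("sd must be >= 0")
  structure(
    list(columns = columns, rows = as.numeric(rows), sd = as.numeric(sd),
         accepted_observations = accepted_observations),
    class = "boundary_trace"
  )
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("<boundary_trace> cols %d..%d | rows %.1f..%.1f | mean sd %.2f px\n",
              min(x$columns), max(x$columns), min(x$rows), max(x$rows),
              mean(x$sd)))
  invisible(x)
}

# Interpolated row at (possibly fractional) column positions.
trace_row_at <- function(trace, columns) {
  linear_interp(trace$columns, trace$rows, columns)
}

#' Construct a segmentation (pair of traces plus geometry)
#'
#' @param rpe_c,c_s [boundary_trace] objects for the upper (RPE-C) and lower
#'   (C-S) choroid boundaries. They must share a common column span
#'   containing the fovea, and `c_s` must lie strictly below `rpe_c`
#'   (larger row indices) on that span.
#' @param lateral_scale,axial_scale micrometres per pixel.
#' @param fovea_column fovea reference column (1-based).
#' @param eye `"right"` (default) or `"left"`; controls temporal/nasal
#'   labelling of lateral offsets.
#' @return an object of class `segmentation`.
#' @export
segmentation <- function(rpe_c, c_s, lateral_scale, axial_scale,
                         fovea_column, eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(inherits(rpe_c, "boundary_trace"), inherits(c_s, "boundary_trace"))
  lo <- max(min(rpe_c$columns), min(c_s$columns))
  hi <- min(max(rpe_c$columns), max(c_s$columns))
  if (lo > hi) stop_invalid("traces do not share a common column span")
  if (fovea_column < lo || fovea_column > hi)
    stop_invalid("fovea_column outside the common trace span")
  span <- lo:hi
  if (any(trace_row_at(c_s, span) <= trace_row_at(rpe_c, span)))
    stop_invalid("crossing boundaries: C-S must lie below RPE-C on the span")
  structure(
    list(rpe_c = rpe_c, c_s = c_s, lateral_scale = lateral_scale,
         axial_scale = axial_scale, fovea_column = as.integer(fovea_column),
         eye = eye, span = c(lo, hi)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> span cols %d..%d | fovea col %d | %s eye\n",
              x$span[1], x$span[2], x$fovea_column, x$eye))
  invisible(x)
}
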