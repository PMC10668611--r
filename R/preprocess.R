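# Preprocessing pipeline: median denoising -> contrast-limited adaptive
# histogram equalization -> polarity-selected vertical edge maps cleaned by
# morphological opening and small-component removal.

#' Median-filter denoising
#'
#' Replaces each pixel by the median of its `window x window` neighbourhood
#' with reflected borders. Metadata and scales pass through untouched.
#'
#' @param scan a [bscan].
#' @param window odd neighbourhood size, `>= 1`.
#' @return a denoised [bscan].
#' @export
denoise_median <- function(scan, window = 5L) {
  stopifnot(inherits(scan, "bscan"))
  check_scalar(window, "window", positive = TRUE, integerish = TRUE)
  if (window %% 2 == 0) stop_invalid("window must be odd")
  if (window == 1) return(scan)
  update_pixels(scan, .median_filter_cpp(scan$pixels, as.integer(window)))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipped histograms (excess mass
#' redistributed uniformly) and bilinear blending of the per-tile mappings.
#' Output intensities stay in `[0, 1]`.
#'
#' @param scan a [bscan] (intensities in `[0, 1]`).
#' @param clip_limit fraction in `(0, 1]` of a tile's pixel count allowed
#'   in any single histogram bin before clipping.
#' @param tiles integer `c(rows, cols)` tile grid.
#' @param nbins number of histogram bins.
#' @return a contrast-enhanced [bscan].
#' @export
enhance_clahe <- function(scan, clip_limit = 0.02, tiles = c(8L, 8L),
                          nbins = 256L) {
  stopifnot(inherits(scan, "bscan"))
  if (clip_limit <= 0 || clip_limit > 1)
    stop_invalid("clip_limit must be in (0, 1]")
  tiles <- as.integer(tiles)
  if (any(tiles < 1)) stop_invalid("tiles must be >= 1 in both dimensions")
  img <- scan$pixels
  nr <- nrow(img); nc <- ncol(img)
  if (tiles[1] > nr || tiles[2] > nc)
    stop_invalid("tile grid finer than the image")
  tr <- tiles[1]; tc <- tiles[2]
  # tile boundaries and centres
  row_edges <- round(seq(0, nr, length.out = tr + 1))
  col_edges <- round(seq(0, nc, length.out = tc + 1))
  row_ctr <- (row_edges[-1] + row_edges[-(tr + 1)] + 1) / 2
  col_ctr <- (col_edges[-1] + col_edges[-(tc + 1)] + 1) / 2
  bin <- pmin(pmax(floor(img * nbins) + 1L, 1L), nbins)
  # per-tile clipped-equalization lookup tables: nbins x (tr*tc)
  luts <- matrix(0, nbins, tr * tc)
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      rs <- (row_edges[i] + 1):row_edges[i + 1]
      cs <- (col_edges[j] + 1):col_edges[j + 1]
      h <- tabulate(bin[rs, cs], nbins)
      npix <- sum(h)
      clip <- max(1, clip_limit * npix)
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / nbins
      cdf <- cumsum(h) / sum(h)
      luts[, (j - 1) * tr + i] <- cdf
    }
  }
  # bilinear blend of the four surrounding tile mappings per pixel
  ri <- findInterval(seq_len(nr), row_ctr)          # tile index below
  ci <- findInterval(seq_len(nc), col_ctr)
  r0 <- pmin(pmax(ri, 1L), tr); r1 <- pmin(r0 + (ri >= 1 & ri < tr), tr)
  r1[ri < 1] <- 1L
  c0 <- pmin(pmax(ci, 1L), tc); c1 <- pmin(c0 + (ci >= 1 & ci < tc), tc)
  c1[ci < 1] <- 1L
  wr <- ifelse(r1 > r0,
               (seq_len(nr) - row_ctr[r0]) / (row_ctr[r1] - row_ctr[r0]), 0)
  wc <- ifelse(c1 > c0,
               (seq_len(nc) - col_ctr[c0]) / (col_ctr[c1] - col_ctr[c0]), 0)
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)
  out <- matrix(0, nr, nc)
  WR <- matrix(wr, nr, nc)
  WC <- matrix(wc, nr, nc, byrow = TRUE)
  lut_at <- function(rtile, ctile) {
    # rtile, ctile are per-row / per-column tile indices
    tile_idx <- (matrix(ctile, nr, nc, byrow = TRUE) - 1) * tr +
      matrix(rtile, nr, nc)
    matrix(luts[cbind(as.vector(bin), as.vector(tile_idx))], nr, nc)
  }
  out <- (1 - WR) * (1 - WC) * lut_at(r0, c0) +
         (1 - WR) * WC * lut_at(r0, c1) +
         WR * (1 - WC) * lut_at(r1, c0) +
         WR * WC * lut_at(r1, c1)
  update_pixels(scan, pmin(pmax(out, 0), 1))
}

# separable Gaussian blur with reflected borders (sigma in pixels)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(m) {   # along rows (first dimension)
    n <- nrow(m)
    idx <- vapply(-h:h, function(d) reflect_idx(seq_len(n) + d, n),
                  integer(n))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

reflect_idx <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n - i + 1, i)
  as.integer(pmin(pmax(i, 1), n))
}

# binary erosion / dilation with a rows x cols box structuring element
morph_box <- function(mask, se = c(1L, 3L), op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(mask); nc <- ncol(mask)
  hr <- (se[1] - 1) %/% 2; hc <- (se[2] - 1) %/% 2
  acc <- mask
  pad <- op == "dilate"   # outside counts as FALSE for both ops
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  for (dr in -hr:hr) for (dc in -hc:hc) {
    if (dr == 0 && dc == 0) next
    s <- shift(mask, dr, dc)
    acc <- if (op == "erode") acc & s else acc | s
  }
  acc
}

#' Polarity-selected vertical edge map
#'
#' Computes the signed central-difference derivative along the axial (row)
#' direction of an optionally Gaussian-smoothed image, keeps the polarity of
#' interest (negatives clipped to zero), then cleans the binary support by a
#' morphological opening with a horizontal structuring element followed by
#' removal of small 8-connected components. Surviving pixels keep their
#' gradient magnitudes.
#'
#' @param scan a [bscan].
#' @param polarity `"dark_to_bright"` (intensity increasing downward; the
#'   choroid-sclera transition) or `"bright_to_dark"` (the RPE-choroid
#'   transition).
#' @param smoothing_scale Gaussian sigma in pixels applied before
#'   differentiation (`0` disables smoothing).
#' @param min_component_px connected responses smaller than this are
#'   removed.
#' @param min_strength support threshold as a fraction of the maximum
#'   response; suppresses speckle-scale gradients before opening.
#' @param opening_se structuring element `c(rows, cols)` of the opening.
#' @return list of class `edge_map`: `gradient` (nonnegative matrix, same
#'   shape as the image), `polarity`, and the scan's scales.
#' @export
build_edge_map <- function(scan, polarity = c("dark_to_bright",
                                              "bright_to_dark"),
                           smoothing_scale = 2, min_component_px = 5L,
                           min_strength = 0.05, opening_se = c(1L, 3L)) {
  stopifnot(inherits(scan, "bscan"))
  polarity <- match.arg(polarity)
  check_scalar(smoothing_scale, "smoothing_scale", nonneg = TRUE)
  img <- gaussian_blur(scan$pixels, smoothing_scale)
  nr <- nrow(img)
  d <- matrix(0, nr, ncol(img))
  d[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  if (polarity == "bright_to_dark") d <- -d
  d[d < 0] <- 0
  if (max(d) > 0) {
    support <- d > min_strength * max(d)
    support <- morph_box(morph_box(support, opening_se, "erode"),
                         opening_se, "dilate")
    if (min_component_px > 1)
      support <- .filter_components_cpp(support, as.integer(min_component_px))
    d[!support] <- 0
  }
  structure(
    list(gradient = d, polarity = polarity,
         lateral_scale = scan$lateral_scale, axial_scale = scan$axial_scale),
    class = "edge_map"
  )
}

#' Run the full preprocessing pipeline for one boundary
#'
#' Denoise, contrast-enhance, and build the edge map with the polarity
#' matching the requested junction.
#'
#' @param scan a [bscan].
#' @param boundary `"rpe_c"` (bright-to-dark) or `"c_s"` (dark-to-bright).
#' @param median_window,clip_limit,tiles,smoothing_scale,min_component_px
#'   parameters forwarded to the pipeline stages.
#' @return an `edge_map`.
#' @export
preprocess_bscan <- function(scan, boundary = c("c_s", "rpe_c"),
                             median_window = 5L, clip_limit = 0.005,
                             tiles = c(8L, 8L), smoothing_scale = 2,
                             min_component_px = 5L) {
  boundary <- match.arg(boundary)
  scan <- denoise_median(scan, median_window)
  scan <- enhance_clahe(scan, clip_limit, tiles)
  build_edge_map(
    scan,
    polarity = if (boundary == "c_s") "dark_to_bright" else "bright_to_dark",
    smoothing_scale = smoothing_scale,
    min_component_px = min_component_px
  )
}
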