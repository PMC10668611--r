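# Synthetic EDI-OCT world: layered speckle B-scans with known junction
# curves, a simulated manual grader with angular error, and longitudinal
# cohorts with known choroid-renal-marker effect sizes.

#' Parameters for the synthetic B-scan generator
#'
#' Defaults reproduce the acquisition geometry of a Spectralis horizontal
#' line EDI-OCT scan: a 768 x 768 pixel image covering 8.7 mm laterally
#' (8700/768 = 11.33 um/px) with a nominal axial scale of 3.87 um/px.
#'
#' @param height_px,width_px image dimensions in pixels.
#' @param lateral_scale,axial_scale micrometres per pixel.
#' @param fovea_column fovea reference column (1-based).
#' @param rpe_curve,cs_curve functions mapping column index to sub-pixel row
#'   for the RPE-C and C-S junctions. `cs_curve(x) > rpe_curve(x)` must hold
#'   everywhere (the choroid has positive thickness).
#' @param layer_intensities named vector of mean gray levels in `[0, 1]` for
#'   `retina`, `rpe`, `choroid` and `sclera`. Defaults put a bright RPE band
#'   above a darker choroid and a brighter sclera, giving a bright-to-dark
#'   axial transition at RPE-C and dark-to-bright at C-S.
#' @param rpe_band_px thickness of the hyperreflective RPE band, pixels.
#' @param vessel_count number of dark elliptical vessel cross-sections
#'   placed uniformly inside the choroid band.
#' @param speckle_strength dimensionless `>= 0`; multiplicative gamma
#'   speckle with shape `1/speckle_strength^2` (mean 1), so 0 disables it.
#' @param shadow_columns list of `c(start, width)` column spans whose
#'   intensity is attenuated, emulating vessel shadowing.
#' @param seed integer seed; identical parameters give bit-identical images.
#' @return an object of class `synth_scan_params`.
#' @export
synth_scan_params <- function(height_px = 768L, width_px = 768L,
                              lateral_scale = 8700 / 768,
                              axial_scale = 3.87,
                              fovea_column = NULL,
                              rpe_curve = function(x) rep(300, length(x)),
                              cs_curve = function(x) rep(400, length(x)),
                              layer_intensities = c(retina = 0.30, rpe = 0.90,
                                                    choroid = 0.40,
                                                    sclera = 0.65),
                              rpe_band_px = 6L,
                              vessel_count = 0L,
                              speckle_strength = 0,
                              shadow_columns = list(),
                              seed = 1L) {
  check_scalar(height_px, "height_px", positive = TRUE, integerish = TRUE)
  check_scalar(width_px, "width_px", positive = TRUE, integerish = TRUE)
  check_scalar(lateral_scale, "lateral_scale", positive = TRUE)
  check_scalar(axial_scale, "axial_scale", positive = TRUE)
  check_scalar(speckle_strength, "speckle_strength", nonneg = TRUE)
  check_scalar(vessel_count, "vessel_count", nonneg = TRUE, integerish = TRUE)
  if (is.null(fovea_column)) fovea_column <- floor(width_px / 2)
  needed <- c("retina", "rpe", "choroid", "sclera")
  if (!all(needed %in% names(layer_intensities)))
    stop_invalid("layer_intensities must name retina, rpe, choroid, sclera")
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         lateral_scale = lateral_scale, axial_scale = axial_scale,
         fovea_column = as.integer(fovea_column),
         rpe_curve = rpe_curve, cs_curve = cs_curve,
         layer_intensities = layer_intensities,
         rpe_band_px = as.integer(rpe_band_px),
         vessel_count = as.integer(vessel_count),
         speckle_strength = speckle_strength,
         shadow_columns = shadow_columns, seed = as.integer(seed)),
    class = "synth_scan_params"
  )
}

# Render a piecewise-constant layered column with linear blending across
# each (sub-pixel) boundary row. rows is 1..height; returns intensities.
render_column <- function(height, rpe, cs, band, li) {
  ints <- numeric(height)
  rows <- seq_len(height)
  band_top <- rpe - band
  # region assignment by pixel centre, then alpha-blend boundary pixels
  ints[rows < band_top] <- li[["retina"]]
  ints[rows >= band_top & rows < rpe] <- li[["rpe"]]
  ints[rows >= rpe & rows < cs] <- li[["choroid"]]
  ints[rows >= cs] <- li[["sclera"]]
  blend <- function(boundary, upper, lower) {
    r <- floor(boundary)
    if (r >= 1 && r <= height) {
      frac <- boundary - r
      ints[r] <<- frac * upper + (1 - frac) * lower
    }
  }
  blend(band_top, li[["retina"]], li[["rpe"]])
  blend(rpe, li[["rpe"]], li[["choroid"]])
  blend(cs, li[["choroid"]], li[["sclera"]])
  ints
}

#' Generate a synthetic EDI-OCT B-scan with known ground truth
#'
#' Builds a layered image (retina / bright RPE band / choroid / sclera)
#' whose junction rows follow `rpe_curve` and `cs_curve`, adds dark
#' elliptical vessels inside the choroid, multiplicative gamma speckle, and
#' attenuated shadow column spans, then quantizes to 8 bits. The returned
#' ground truth holds the exact curves as [boundary_trace] objects.
#'
#' @param params a [synth_scan_params] object.
#' @return list with elements `scan` (a [bscan]) and `truth` (list with
#'   `rpe_c`, `c_s` [boundary_trace]s, `fovea_column`, `lateral_scale`,
#'   `axial_scale`).
#' @export
generate_bscan <- function(params) {
  stopifnot(inherits(params, "synth_scan_params"))
  h <- params$height_px; w <- params$width_px
  cols <- seq_len(w)
  rpe <- params$rpe_curve(cols)
  cs <- params$cs_curve(cols)
  if (length(rpe) != w || length(cs) != w)
    stop_invalid("curves must return one row per column")
  if (any(cs <= rpe))
    stop_invalid("cs_curve must lie strictly below rpe_curve everywhere")
  if (any(rpe < 1 + params$rpe_band_px) || any(cs > h))
    stop_invalid("curves leave the image bounds")
  li <- params$layer_intensities
  img <- vapply(cols, function(c0)
    render_column(h, rpe[c0], cs[c0], params$rpe_band_px, li),
    numeric(h))
  with_seed(params$seed, {
    if (params$vessel_count > 0) {
      for (k in seq_len(params$vessel_count)) {
        cx <- runif(1, 1, w)
        c0 <- max(1L, min(w, as.integer(round(cx))))
        margin <- 3
        lo <- rpe[c0] + margin; hi <- cs[c0] - margin
        if (hi <= lo) next
        cy <- runif(1, lo, hi)
        a <- runif(1, 4, 14)   # lateral semi-axis, px
        b <- runif(1, 3, 8)    # axial semi-axis, px
        cr <- max(1L, floor(cx - a)):min(w, ceiling(cx + a))
        rr <- max(1L, floor(cy - b)):min(h, ceiling(cy + b))
        dd <- outer((rr - cy)^2 / b^2, (cr - cx)^2 / a^2, "+")
        sub <- img[rr, cr, drop = FALSE]
        sub[dd <= 1] <- sub[dd <= 1] * 0.35
        img[rr, cr] <- sub
      }
    }
    if (params$speckle_strength > 0) {
      shape <- 1 / params$speckle_strength^2
      img <- img * matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
    }
  })
  for (sh in params$shadow_columns) {
    span <- max(1L, sh[1]):min(w, sh[1] + sh[2] - 1L)
    img[, span] <- img[, span] * 0.45
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255   # 8-bit quantization
  scan <- bscan(img, params$lateral_scale, params$axial_scale,
                params$fovea_column,
                meta = list(synthetic = TRUE, seed = params$seed))
  truth <- list(
    rpe_c = boundary_trace(cols, rpe),
    c_s = boundary_trace(cols, cs),
    fovea_column = params$fovea_column,
    lateral_scale = params$lateral_scale,
    axial_scale = params$axial_scale
  )
  list(scan = scan, truth = truth)
}

#' Parameters of the simulated manual grader
#'
#' The grader marks fovea-referenced lateral landmarks with Gaussian jitter
#' and measures along a direction rotated away from the true local
#' perpendicular by a normally distributed angular error. Defaults follow
#' the empirical angular-error distribution of a trained human grader:
#' mean 0.5 degrees, SD 2.5 degrees.
#'
#' @param angle_mean,angle_sd degrees; mean and SD of the angular error.
#' @param landmark_jitter_sd micrometres; SD of lateral landmark jitter.
#' @param seed integer seed.
#' @export
grader_params <- function(angle_mean = 0.5, angle_sd = 2.5,
                          landmark_jitter_sd = 0, seed = 1L) {
  check_scalar(angle_sd, "angle_sd", nonneg = TRUE)
  check_scalar(landmark_jitter_sd, "landmark_jitter_sd", nonneg = TRUE)
  structure(
    list(angle_mean = angle_mean, angle_sd = angle_sd,
         landmark_jitter_sd = landmark_jitter_sd, seed = as.integer(seed)),
    class = "grader_params"
  )
}

#' Simulate manual caliper measurements on known ground truth
#'
#' For each fovea-referenced lateral offset, anchors a caliper on the RPE-C
#' curve at the (jittered) landmark, rotates the local inward perpendicular
#' by an angular-error draw, and extends the caliper to its intersection
#' with the C-S curve. Angles are applied in physical micrometre space; the
#' anisotropic pixel scales only enter through the coordinate conversion.
#'
#' @param truth ground truth as returned by [generate_bscan].
#' @param grader a [grader_params] object.
#' @param offsets_um lateral offsets from the fovea in micrometres
#'   (negative = temporal for a right eye).
#' @return data frame with one row per offset: anchor coordinates (um),
#'   direction components, caliper `length_um`, the drawn signed
#'   `angle_deg`, `location_label`, and `valid` (FALSE when the caliper
#'   leaves the image before crossing C-S).
#' @export
simulate_manual_calipers <- function(truth, grader, offsets_um) {
  stopifnot(inherits(grader, "grader_params"))
  lat <- truth$lateral_scale; ax <- truth$axial_scale
  x_um <- (truth$rpe_c$columns - 1) * lat
  rpe_um <- truth$rpe_c$rows * ax
  cs_um <- trace_row_at(truth$c_s, truth$rpe_c$columns) * ax
  fovea_x <- (truth$fovea_column - 1) * lat
  n <- length(offsets_um)
  with_seed(grader$seed, {
    jit <- rnorm(n, 0, grader$landmark_jitter_sd)
    ang <- rnorm(n, grader$angle_mean, grader$angle_sd)
  })
  out <- lapply(seq_len(n), function(i) {
    xt <- fovea_x + offsets_um[i] + jit[i]
    if (xt < min(x_um) || xt > max(x_um))
      stop_invalid("offset outside the lateral field of view")
    anchor <- c(xt, linear_interp(x_um, rpe_um, xt))
    slope <- local_tangent_slope(x_um, rpe_um, xt, window = 50)
    dir <- rotate_deg(inward_normal(slope), ang[i])
    len <- ray_polyline_intersection(anchor, dir, x_um, cs_um)
    data.frame(
      offset_um = offsets_um[i], anchor_x_um = anchor[1],
      anchor_y_um = anchor[2], dir_x = dir[1], dir_y = dir[2],
      length_um = if (is.na(len)) NA_real_ else len,
      angle_deg = ang[i],
      location_label = location_label(offsets_um[i]),
      valid = !is.na(len)
    )
  })
  do.call(rbind, out)
}

location_label <- function(offset_um, eye = "right") {
  lab <- if (offset_um == 0) "subfoveal"
         else if (offset_um < 0) "temporal" else "nasal"
  if (eye == "left" && lab != "subfoveal")
    lab <- setdiff(c("temporal", "nasal"), lab)
  lab
}

#' Parameters of the synthetic longitudinal cohort generator
#'
#' The stated world follows the structure of a living-donor transplant
#' study: two cohorts (kidney donors and transplant recipients) imaged at
#' baseline and fixed follow-up weeks. Choroidal thickness follows a
#' per-patient random intercept plus a cohort-specific linear ramp reaching
#' the stated 1-year fractional change at week 52 (+14.1% recipients,
#' -4.9% donors by default, the observed automated-CT changes). Renal
#' markers are standardized linear functions of standardized true CT and
#' relative daytime plus a per-patient random intercept and residual noise.
#'
#' @param n_donors,n_recipients patients per cohort.
#' @param visit_weeks follow-up schedule in weeks; must start at 0.
#' @param mean_baseline_ct mean baseline CT, micrometres.
#' @param patient_sd SD of the per-patient CT random intercept, um.
#' @param recipient_1yr_change,donor_1yr_change fractional CT change from
#'   baseline at week 52.
#' @param choroid_marker_slopes named standardized effects of CT on each
#'   marker (`egfr`, `creatinine`, `urea`).
#' @param daytime_effect standardized effect of relative daytime (hours)
#'   on every marker; diurnal choroid variation makes this negative.
#' @param marker_re_sd SD of the per-patient marker random intercept
#'   (standardized scale).
#' @param noise_sd residual SD of the markers (standardized scale).
#' @param grader_angle_mean,grader_angle_sd angular error (degrees) applied
#'   to the simulated manual CT via the secant relation.
#' @param grader_landmark_sd_um additive manual-CT error SD (um) from
#'   lateral landmark jitter acting through the local thickness gradient of
#'   curved, non-parallel boundaries. On a flat choroid the secant term
#'   alone is sub-micrometre at 2.5 degrees; on real anatomy the angular
#'   and landmark errors are what make manual CT noisier than automated
#'   CT, so this term carries that mechanism into the cohort world.
#' @param auto_noise_sd small residual noise SD (um) on automated CT.
#' @param daytime_sd SD (hours) of visit daytime around each patient's
#'   baseline daytime.
#' @param seed integer seed.
#' @export
cohort_params <- function(n_donors = 9L, n_recipients = 9L,
                          visit_weeks = c(0, 1, 4, 8, 12, 52),
                          mean_baseline_ct = 300, patient_sd = 40,
                          recipient_1yr_change = 0.141,
                          donor_1yr_change = -0.049,
                          choroid_marker_slopes = c(egfr = 1.0,
                                                    creatinine = -1.0,
                                                    urea = -1.0),
                          daytime_effect = -0.4,
                          marker_re_sd = 0.5, noise_sd = 0.5,
                          grader_angle_mean = 0.5, grader_angle_sd = 2.5,
                          grader_landmark_sd_um = 15,
                          auto_noise_sd = 2, daytime_sd = 1,
                          seed = 1L) {
  if (visit_weeks[1] != 0)
    stop_invalid("visit_weeks must start at 0 (baseline)")
  if (any(visit_weeks < 0)) stop_invalid("visit weeks must be nonnegative")
  for (nm in c("patient_sd", "marker_re_sd", "noise_sd", "auto_noise_sd",
               "daytime_sd", "grader_angle_sd", "grader_landmark_sd_um"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  mk <- c("egfr", "creatinine", "urea")
  if (!all(mk %in% names(choroid_marker_slopes)))
    stop_invalid("choroid_marker_slopes must name egfr, creatinine, urea")
  structure(
    list(n_donors = as.integer(n_donors),
         n_recipients = as.integer(n_recipients),
         visit_weeks = visit_weeks, mean_baseline_ct = mean_baseline_ct,
         patient_sd = patient_sd,
         recipient_1yr_change = recipient_1yr_change,
         donor_1yr_change = donor_1yr_change,
         choroid_marker_slopes = choroid_marker_slopes[mk],
         daytime_effect = daytime_effect, marker_re_sd = marker_re_sd,
         noise_sd = noise_sd, grader_angle_mean = grader_angle_mean,
         grader_angle_sd = grader_angle_sd,
         grader_landmark_sd_um = grader_landmark_sd_um,
         auto_noise_sd = auto_noise_sd,
         daytime_sd = daytime_sd, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# marker location/scale used to map standardized latent markers onto
# clinically plausible units (eGFR mL/min/1.73m2, creatinine umol/L,
# urea mmol/L)
marker_units <- function() {
  list(location = c(egfr = 60, creatinine = 150, urea = 10),
       scale = c(egfr = 25, creatinine = 80, urea = 4))
}

#' Generate a synthetic longitudinal cohort table
#'
#' @param params a [cohort_params] object.
#' @return data frame with one row per patient-visit: `patient`, `cohort`,
#'   `visit_week`, `daytime`, `relative_daytime`, `age`, `sex`,
#'   `scan_focus`, `true_ct`, `auto_ct`, `manual_ct`, `auto_ca`, `egfr`,
#'   `creatinine`, `urea`. The `truth` attribute stores the generating
#'   coefficients, including the implied coefficients on the z-scored
#'   response scale used by [fit_lme] (`beta_z`), for recovery tests.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  pats <- data.frame(
    patient = c(sprintf("D%02d", seq_len(p$n_donors)),
                sprintf("R%02d", seq_len(p$n_recipients))),
    cohort = rep(c("donor", "recipient"), c(p$n_donors, p$n_recipients)),
    stringsAsFactors = FALSE
  )
  nw <- length(p$visit_weeks)
  with_seed(p$seed, {
    pats$age <- rnorm(nrow(pats), 48, 12)
    pats$sex <- rbinom(nrow(pats), 1, 0.5)
    pats$scan_focus <- rnorm(nrow(pats), 0, 1.5)
    pats$b_ct <- rnorm(nrow(pats), 0, p$patient_sd)
    pats$u_marker <- rnorm(nrow(pats), 0, p$marker_re_sd)
    pats$base_daytime <- runif(nrow(pats), 9, 17)
    tab <- pats[rep(seq_len(nrow(pats)), each = nw), ]
    tab$visit_week <- rep(p$visit_weeks, nrow(pats))
    rel <- rnorm(nrow(tab), 0, p$daytime_sd)
    rel[tab$visit_week == 0] <- 0
    tab$relative_daytime <- rel
    tab$daytime <- tab$base_daytime + rel
    change <- ifelse(tab$cohort == "recipient",
                     p$recipient_1yr_change, p$donor_1yr_change)
    tab$true_ct <- (p$mean_baseline_ct + tab$b_ct) *
      (1 + change * tab$visit_week / 52)
    tab$auto_ct <- tab$true_ct + rnorm(nrow(tab), 0, p$auto_noise_sd)
    theta <- rnorm(nrow(tab), p$grader_angle_mean, p$grader_angle_sd)
    tab$manual_ct <- tab$true_ct / cos(theta * pi / 180) +
      rnorm(nrow(tab), 0, p$grader_landmark_sd_um)
    # CA over the 6000-um ETDRS window implied by a locally uniform choroid
    tab$auto_ca <- tab$auto_ct * 6000 / 1e6
    z_ct <- if (sd(tab$true_ct) > 0) as.numeric(scale(tab$true_ct))
            else tab$true_ct * 0
    z_day <- if (sd(tab$relative_daytime) > 0)
      as.numeric(scale(tab$relative_daytime)) else tab$relative_daytime * 0
    eps <- matrix(rnorm(nrow(tab) * 3, 0, p$noise_sd), ncol = 3)
    colnames(eps) <- c("egfr", "creatinine", "urea")
    mu <- marker_units()
    latent <- sapply(c("egfr", "creatinine", "urea"), function(m) {
      p$choroid_marker_slopes[[m]] * z_ct + p$daytime_effect * z_day +
        tab$u_marker + eps[, m]
    })
    for (m in colnames(latent))
      tab[[m]] <- mu$location[[m]] + mu$scale[[m]] * latent[, m]
  })
  rownames(tab) <- NULL
  tab$b_ct <- tab$u_marker <- tab$base_daytime <- NULL
  # implied true coefficients on the z-scored response scale that fit_lme
  # estimates: latent slopes divided by the realized latent-marker SD
  sd_latent <- apply(latent, 2, sd)
  truth <- list(
    latent_slopes = p$choroid_marker_slopes,
    daytime_effect = p$daytime_effect,
    beta_z = lapply(setNames(colnames(latent), colnames(latent)), function(m)
      c(choroid = unname(p$choroid_marker_slopes[[m]] / sd_latent[[m]]),
        daytime = unname(p$daytime_effect / sd_latent[[m]]))),
    marker_location = mu$location, marker_scale = mu$scale,
    z_ct = z_ct, z_day = z_day
  )
  attr(tab, "truth") <- truth
  tab
}
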