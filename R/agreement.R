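# Method-comparison statistics between paired manual and automated CT:
# residuals, MAE, Pearson, ICC(3,1), Passing-Bablok, Bland-Altman,
# major-discrepancy flagging and longitudinal angular-deviation series.

#' Paired manual/automated measurements
#'
#' @param x reference (manual) values, micrometres.
#' @param y test (automated) values, micrometres.
#' @param ids optional data frame of `(patient, visit, location)` keys.
#' @return object of class `paired_measurements`.
#' @export
paired_measurements <- function(x, y, ids = NULL) {
  if (length(x) != length(y))
    stop_invalid("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("missing or non-finite pairs are not allowed")
  structure(list(x = as.numeric(x), y = as.numeric(y), ids = ids),
            class = "paired_measurements")
}

as_pairs <- function(pairs) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  stop_invalid("expected a paired_measurements object")
}

#' Residuals of paired measurements (automated minus manual)
#'
#' The sign convention is fixed: a positive residual means the automated
#' measurement is larger than the manual one.
#'
#' @param pairs a [paired_measurements].
#' @return numeric vector `y - x` in micrometres.
#' @export
ct_residuals <- function(pairs) {
  pairs <- as_pairs(pairs)
  if (length(pairs$x) == 0L) stop_invalid("no pairs")
  pairs$y - pairs$x
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-rater, consistency form (Shrout-Fleiss):
#' `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)` from the
#' two-way ANOVA decomposition with raters as fixed effects. Insensitive to
#' a fixed shift between raters.
#'
#' @param x,y paired ratings.
#' @return ICC(3,1) estimate.
#' @export
icc31 <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 pairs for ICC")
  dat <- cbind(x, y)
  k <- 2
  grand <- mean(dat)
  subj_means <- rowMeans(dat)
  rater_means <- colMeans(dat)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((dat - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  msb <- ss_subj / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse)
}

#' Agreement summary statistics
#'
#' @param pairs a [paired_measurements].
#' @return list with `residual_mean`, `residual_sd`, `mae_mean`, `mae_sd`
#'   (micrometres; SDs use the n-1 denominator), `pearson_r`, `icc_3_1`.
#' @export
summary_stats <- function(pairs) {
  pairs <- as_pairs(pairs)
  if (length(pairs$x) < 3L) stop_invalid("need at least 3 pairs")
  if (sd(pairs$x) == 0 || sd(pairs$y) == 0)
    stop_invalid("correlation undefined: zero variance in a series")
  r <- ct_residuals(pairs)
  list(
    residual_mean = mean(r), residual_sd = sd(r),
    mae_mean = mean(abs(r)), mae_sd = sd(abs(r)),
    pearson_r = cor(pairs$x, pairs$y),
    icc_3_1 = icc31(pairs$x, pairs$y)
  )
}

#' Passing-Bablok regression
#'
#' Rank-based method-comparison regression. The slope is the shifted median
#' of all pairwise slopes (slopes of exactly -1 excluded; ties `0/0`
#' dropped; the offset `K` counts slopes below -1), the intercept the
#' median of `y - slope * x`. Confidence intervals use the original
#' rank-based analytic formula.
#'
#' @param pairs a [paired_measurements].
#' @param conf_level confidence level, default 0.95.
#' @return list with `slope`, `slope_ci`, `intercept`, `intercept_ci`, `n`.
#' @export
passing_bablok <- function(pairs, conf_level = 0.95) {
  pairs <- as_pairs(pairs)
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 pairs")
  if (length(unique(x)) < 2L) stop_invalid("all x identical")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- ifelse(dx == 0 & dy == 0, NA_real_,
              ifelse(dx == 0, sign(dy) * Inf, dy / dx))
  s <- s[!is.na(s) & s != -1]
  s <- sort(s)           # +/- Inf sort to the ends
  N <- length(s)
  if (N < 1L) stop_invalid("insufficient distinct points")
  K <- sum(s < -1)
  med_shift <- function(offset) {
    # median of s with index shift `offset` (1-based positions)
    if (N %% 2 == 1) s[(N + 1) / 2 + offset]
    else mean(s[N / 2 + offset + 0:1])
  }
  b <- med_shift(K)
  w <- qnorm(1 - (1 - conf_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1L, as.integer(round((N - w) / 2)))
  m2 <- min(N, N - m1 + 1L)
  slope_ci <- c(s[min(N, m1 + K)], s[min(N, m2 + K)])
  a <- median(y - b * x)
  intercept_ci <- c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))
  list(slope = b, slope_ci = slope_ci, intercept = a,
       intercept_ci = intercept_ci, n = n)
}

#' Bland-Altman limits of agreement
#'
#' @param residuals numeric vector of paired differences (automated minus
#'   manual, micrometres).
#' @param k limits-of-agreement multiplier (default 1.96).
#' @return list with `mean` and `loa = c(low, high)`.
#' @export
bland_altman <- function(residuals, k = 1.96) {
  if (length(residuals) < 3L) stop_invalid("need at least 3 residuals")
  m <- mean(residuals); s <- sd(residuals)
  list(mean = m, loa = c(m - k * s, m + k * s))
}

#' Flag major discrepancies
#'
#' A residual is a major discrepancy when its absolute value strictly
#' exceeds the threshold (default 32 um, the published interobserver
#' variability bound for EDI-OCT choroid grading).
#'
#' @param residuals numeric vector, micrometres.
#' @param threshold_um positive threshold.
#' @return list with logical `flags`, `n_flagged`, `fraction`, `percent`.
#' @export
flag_major <- function(residuals, threshold_um = 32) {
  check_scalar(threshold_um, "threshold_um", positive = TRUE)
  flags <- abs(residuals) > threshold_um
  list(flags = flags, n_flagged = sum(flags),
       fraction = mean(flags), percent = 100 * mean(flags),
       threshold_um = threshold_um)
}

#' Longitudinal angular-deviation series
#'
#' Unsigned within-patient angular deviations relative to baseline: for
#' every patient/location, `|angle(visit) - angle(baseline)|` at each
#' follow-up visit, summarized per visit by the empirical mean and SD
#' across patients and locations.
#'
#' @param angles data frame with columns `patient`, `visit` (sortable;
#'   baseline = smallest value, required for every patient), optional
#'   `location`, and `angle_deg`.
#' @return list with `deviations` (long data frame incl. `deviation_deg`)
#'   and `per_visit` (data frame `visit`, `mean_deg`, `sd_deg`, `n`).
#' @export
angular_deviation_series <- function(angles) {
  req <- c("patient", "visit", "angle_deg")
  if (!all(req %in% names(angles)))
    stop_invalid("angles needs columns patient, visit, angle_deg")
  if (is.null(angles$location)) angles$location <- "all"
  base_visit <- min(angles$visit)
  key <- interaction(angles$patient, angles$location, drop = TRUE)
  has_base <- tapply(angles$visit, key, function(v) base_visit %in% v)
  if (!all(has_base))
    stop_invalid("baseline visit missing for some patient/location")
  base_lookup <- angles[angles$visit == base_visit, ]
  bl <- setNames(base_lookup$angle_deg,
                 interaction(base_lookup$patient, base_lookup$location,
                             drop = FALSE))
  dev <- angles[angles$visit != base_visit, ]
  dev$deviation_deg <- abs(dev$angle_deg - bl[as.character(
    interaction(dev$patient, dev$location, drop = FALSE))])
  per_visit <- do.call(rbind, lapply(split(dev, dev$visit), function(d)
    data.frame(visit = d$visit[1], mean_deg = mean(d$deviation_deg),
               sd_deg = sd(d$deviation_deg), n = nrow(d))))
  rownames(per_visit) <- NULL
  list(deviations = dev, per_visit = per_visit)
}

#' Full agreement report
#'
#' Bundles all method-comparison statistics for a set of paired
#' measurements into one object.
#'
#' @param pairs a [paired_measurements].
#' @param threshold_um major-discrepancy threshold (default 32 um).
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, threshold_um = 32) {
  pairs <- as_pairs(pairs)
  res <- ct_residuals(pairs)
  ss <- summary_stats(pairs)
  pb <- passing_bablok(pairs)
  ba <- bland_altman(res)
  fl <- flag_major(res, threshold_um)
  structure(
    list(n = length(res),
         residual_mean = ss$residual_mean, residual_sd = ss$residual_sd,
         mae_mean = ss$mae_mean, mae_sd = ss$mae_sd,
         pearson_r = ss$pearson_r, icc_3_1 = ss$icc_3_1,
         pb_slope = pb$slope, pb_slope_ci = pb$slope_ci,
         pb_intercept = pb$intercept, pb_intercept_ci = pb$intercept_ci,
         ba_mean = ba$mean, ba_loa = ba$loa,
         n_flagged = fl$n_flagged, flag_percent = fl$percent,
         flag_threshold_um = threshold_um),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n))
  cat(sprintf("  residual  %.2f +/- %.2f um | MAE %.2f +/- %.2f um\n",
              x$residual_mean, x$residual_sd, x$mae_mean, x$mae_sd))
  cat(sprintf("  Pearson r %.3f | ICC(3,1) %.3f\n", x$pearson_r, x$icc_3_1))
  cat(sprintf("  Passing-Bablok slope %.3f (%.3f, %.3f), intercept %.2f (%.2f, %.2f) um\n",
              x$pb_slope, x$pb_slope_ci[1], x$pb_slope_ci[2],
              x$pb_intercept, x$pb_intercept_ci[1], x$pb_intercept_ci[2]))
  cat(sprintf("  Bland-Altman %.2f um, LoA (%.2f, %.2f) um\n",
              x$ba_mean, x$ba_loa[1], x$ba_loa[2]))
  cat(sprintf("  major discrepancies (>|%.0f| um): %d/%d (%.2f%%)\n",
              x$flag_threshold_um, x$n_flagged, x$n, x$flag_percent))
  invisible(x)
}
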