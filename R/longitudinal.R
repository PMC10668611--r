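# Clinical-evaluation stage: percent change from baseline, paired t-tests,
# marker correlations, and random-intercept linear mixed-effects models
# with standardized coefficients and conditional R^2.

#' Percent change from baseline
#'
#' @param baseline,followup values on the same scale; `baseline != 0`.
#'   Vectorized; cohort summaries should average per-patient percent
#'   changes, not take the percent change of means.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline == 0)) stop_invalid("baseline must be nonzero")
  100 * (followup - baseline) / baseline
}

#' Per-patient percent change between two visits
#'
#' @param table cohort table as from [generate_cohort].
#' @param var measurement column (e.g. `"auto_ct"`).
#' @param week follow-up week to compare against baseline (week 0).
#' @return data frame `(patient, cohort, change_pct)` plus a per-cohort
#'   mean/SD/median summary in the `summary` attribute.
#' @export
percent_change_from_baseline <- function(table, var = "auto_ct",
                                         week = 52) {
  base <- table[table$visit_week == 0, c("patient", "cohort", var)]
  fup <- table[table$visit_week == week, c("patient", var)]
  m <- merge(base, fup, by = "patient", suffixes = c("_base", "_fup"))
  m$change_pct <- percent_change(m[[paste0(var, "_base")]],
                                 m[[paste0(var, "_fup")]])
  out <- m[, c("patient", "cohort", "change_pct")]
  smry <- do.call(rbind, lapply(split(out, out$cohort), function(d)
    data.frame(cohort = d$cohort[1], mean_pct = mean(d$change_pct),
               sd_pct = sd(d$change_pct), median_pct = median(d$change_pct),
               n = nrow(d))))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}

#' Paired (dependent-samples) Student's t-test
#'
#' @param a,b paired samples of equal length (`n >= 2`).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("a and b must have equal length")
  if (length(a) < 2L) stop_invalid("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1,
                                 mean_diff = 0))
    stop_invalid("degenerate test: zero-variance nonzero differences")
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Pearson correlations between choroid measures and renal markers
#'
#' Pairwise complete-case Pearson correlation with two-sided p-values for
#' every (choroid measure, marker) pair.
#'
#' @param table cohort table.
#' @param choroid_vars,markers column names.
#' @return list of matrices `r` and `p` (markers in rows).
#' @export
marker_correlations <- function(table,
                                choroid_vars = c("auto_ca", "auto_ct",
                                                 "manual_ct"),
                                markers = c("egfr", "creatinine", "urea")) {
  r <- p <- matrix(NA_real_, length(markers), length(choroid_vars),
                   dimnames = list(markers, choroid_vars))
  for (m in markers) for (v in choroid_vars) {
    ok <- complete.cases(table[[m]], table[[v]])
    if (sum(ok) < 3L) stop_invalid("fewer than 3 complete pairs for ", m)
    if (sd(table[[m]][ok]) == 0 || sd(table[[v]][ok]) == 0)
      stop_invalid("zero variance: correlation undefined for ", m)
    ct <- cor.test(table[[v]][ok], table[[m]][ok])
    r[m, v] <- unname(ct$estimate)
    p[m, v] <- ct$p.value
  }
  list(r = r, p = p)
}

z_score <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Random-intercept linear mixed-effects model with standardized effects
#'
#' Fits `response ~ age + sex + relative_daytime + scan_focus + choroid +
#' (1 | patient)` by REML with the response and continuous covariates
#' z-scored on the analysis subset (sex coded 0/1 then centered), returning
#' standardized coefficients with Wald 95% confidence intervals and the
#' Nakagawa-Schielzeth conditional R^2.
#'
#' @param table cohort table (complete cases on the model variables are
#'   used).
#' @param response marker column name (e.g. `"egfr"`).
#' @param choroid_var choroid measurement column (e.g. `"auto_ct"`).
#' @param covariates additional fixed-effect columns.
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `lme_fit`: data frame `coefficients` (term,
#'   beta, ci_low, ci_high, p), `random_intercept_sd`, `residual_sd`,
#'   `conditional_r2`, `n_obs`, `n_patients`.
#' @export
fit_lme <- function(table, response, choroid_var,
                    covariates = c("age", "sex", "relative_daytime",
                                   "scan_focus"),
                    conf_level = 0.95) {
  vars <- c(response, choroid_var, covariates, "patient")
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop_invalid("missing columns: ",
                                 paste(miss, collapse = ", "))
  d <- table[complete.cases(table[, vars]), vars]
  if (length(unique(d$patient)) < 2L)
    stop_invalid("need at least 2 patients")
  dz <- d
  for (v in c(response, choroid_var, covariates)) {
    if (v == "sex") dz$sex <- d$sex - mean(d$sex)
    else dz[[v]] <- z_score(d[[v]])
  }
  names(dz)[names(dz) == choroid_var] <- ".choroid"
  names(dz)[names(dz) == response] <- ".y"
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(covariates, ".choroid"), collapse = " + "),
    "+ (1 | patient)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dz, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  pvals <- 2 * pnorm(-abs(beta / se))
  terms <- names(beta)
  terms[terms == ".choroid"] <- choroid_var
  terms[terms == "(Intercept)"] <- "intercept"
  coefs <- data.frame(term = terms, beta = unname(beta),
                      ci_low = unname(beta - zc * se),
                      ci_high = unname(beta + zc * se),
                      p = unname(pvals), stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "patient"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- var(as.numeric(
    stats::model.matrix(fit) %*% beta))
  r2c <- (var_fixed + tau2) / (var_fixed + tau2 + sigma2)
  structure(
    list(coefficients = coefs, random_intercept_sd = sqrt(tau2),
         residual_sd = sqrt(sigma2), conditional_r2 = r2c,
         n_obs = nrow(dz), n_patients = length(unique(dz$patient)),
         response = response, choroid_var = choroid_var),
    class = "lme_fit"
  )
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit> %s ~ ... + %s + (1 | patient): %d obs, %d patients\n",
              x$response, x$choroid_var, x$n_obs, x$n_patients))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("  random-intercept SD %.3f | residual SD %.3f | conditional R2 %.3f\n",
              x$random_intercept_sd, x$residual_sd, x$conditional_r2))
  invisible(x)
}

#' Significance by confidence-interval exclusion of zero
#'
#' A term is a statistically significant predictor iff its confidence
#' interval strictly excludes zero (an interval touching zero at a bound is
#' not significant).
#'
#' @param fit an `lme_fit`.
#' @param term term name as it appears in `fit$coefficients$term`.
#' @return logical.
#' @export
significance_by_ci <- function(fit, term) {
  stopifnot(inherits(fit, "lme_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop_invalid("unknown term: ", term)
  row$ci_low > 0 || row$ci_high < 0
}
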