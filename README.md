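# choroidtrace

Automated measurement of the choroid — the vascular layer between the
retinal pigment epithelium (RPE) and the sclera — on enhanced depth
imaging OCT (EDI-OCT) B-scans, for researchers studying choroidal
thickness (CT) and area (CA) as systemic biomarkers (e.g. of renal
function in kidney donors and transplant recipients).

The package covers the full workflow:

* **Synthetic world** — layered speckle B-scans with known ground-truth
  junction curves, a simulated manual grader with normally distributed
  angular error (mean 0.5°, SD 2.5°), and longitudinal cohorts with known
  choroid–renal-marker effect sizes, so everything is testable offline.
* **Segmentation** — each boundary (RPE-C and C-S junctions) is traced as
  a Gaussian-process posterior over lateral position, grown by a
  recursive Bayesian scheme that scores candidate edge pixels by
  image-gradient evidence (a KDE-based weight) and GP model density.
  Preprocessing is median denoising → CLAHE → polarity-selected vertical
  derivative with morphological cleaning.
* **Metrics** — perpendicular and parallel (caliper-mimicking) CT at the
  fovea and ±2000 µm, in micrometres, and CA over the ±3000 µm ETDRS
  strip in mm². On a flat choroid of thickness *t* a caliper at angle θ
  from the perpendicular measures *t*/cos θ — the quadratic error law the
  evaluation reproduces.
* **Agreement** — residuals (automated − manual), MAE, Pearson,
  ICC(3,1), Passing–Bablok regression with rank-based CIs, Bland–Altman
  limits of agreement, the strict |residual| > 32 µm major-discrepancy
  rule, and longitudinal within-patient angular-deviation series.
* **Longitudinal statistics** — percent change from baseline, paired
  t-tests, marker correlations, and random-intercept linear mixed models
  (REML, standardized coefficients, Wald CIs, Nakagawa–Schielzeth
  conditional R²).

## Worked example

```r
library(choroidtrace)

# a 768x768 synthetic B-scan: sinusoidal choroid-sclera junction,
# multiplicative speckle, 10 vessels
p <- synth_scan_params(
  cs_curve = function(x) 420 + 30 * sin(2 * pi * (x - 1) / 767),
  speckle_strength = 0.3, vessel_count = 10, seed = 1)
g <- generate_bscan(p)

# trace both boundaries from their true endpoint pixels
seg <- segment_choroid(
  g$scan,
  rpe_endpoints = rbind(c(1, g$truth$rpe_c$rows[1]),
                        c(768, g$truth$rpe_c$rows[768])),
  cs_endpoints  = rbind(c(1, g$truth$c_s$rows[1]),
                        c(768, g$truth$c_s$rows[768])))
measure_scan(seg)$ct
#>       label offset_um column thickness_um
#> 1  temporal     -2000    207     574.0592
#> 2 subfoveal         0    384     468.2001
#> 3     nasal      2000    561     348.2331
```

The three rows are perpendicular CT at the standard macular locations
(the fovea and 2000 µm temporal/nasal). The scan-level summaries —
`measure_scan(seg)$average_ct_um` = 463.5 µm and `$area_mm2` = 2.78 mm² —
sit within ~1 µm of the ground truth (464.7 µm) despite speckle, vessels
and 8-bit quantization.

Agreement between the simulated manual grader and the automated pathway
on a synthetic cohort:

```r
tab <- generate_cohort(cohort_params(seed = 1))
agreement_report(paired_measurements(tab$manual_ct, tab$auto_ct))
#> <agreement_report> n = 108 pairs
#>   residual  1.29 +/- 17.85 um | MAE 13.79 +/- 11.33 um
#>   Pearson r 0.928 | ICC(3,1) 0.923
#>   Passing-Bablok slope 0.892 (0.827, 0.966), intercept 36.05 (11.91, 56.21) um
#>   Bland-Altman 1.29 um, LoA (-33.69, 36.28) um
#>   major discrepancies (>|32| um): 10/108 (9.26%)

fit_lme(tab, "egfr", "auto_ct")$conditional_r2
#> [1] 0.8299
```

Here residual = automated − manual; the LoA are mean ± 1.96 SD; the mixed
model regresses standardized eGFR on age, sex, relative daytime, scan
focus and standardized automated CT with a per-patient random intercept.

## Command line

```sh
Rscript -e 'choroidtrace::run_cli()' simulate --seed 3 --out out/
Rscript -e 'choroidtrace::run_cli()' segment --image out/bscan.pgm \
    --rpe-endpoints 1,300,768,300 --cs-endpoints 1,420,768,420 --out out/
Rscript -e 'choroidtrace::run_cli()' measure --rpe-trace out/trace_rpe_c.csv \
    --cs-trace out/trace_c_s.csv --fovea-col 384 --out out/
Rscript -e 'choroidtrace::run_cli()' evaluate --pairs pairs.csv --out out/
Rscript -e 'choroidtrace::run_cli()' cohort-stats --response egfr \
    --choroid auto_ct --seed 1 --out out/
```

Images are plain-text PGM (P2) with scales/fovea metadata in comment
lines; traces and tables are CSV; reports are JSON.

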