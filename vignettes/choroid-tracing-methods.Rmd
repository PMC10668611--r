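---
title: "Methods: Gaussian-process choroid tracing and its evaluation"
author: "choroidtrace developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-process choroid tracing and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The choroid is the vascular layer between the retinal pigment epithelium
(RPE) and the sclera. On enhanced depth imaging OCT (EDI-OCT) B-scans its
thickness (CT, micrometres) and area (CA, mm²) respond to systemic
haemodynamics, which makes them candidate biomarkers of renal function in
kidney disease and transplantation. Manual caliper grading of the choroid
is slow and, more importantly, imprecise in a specific way: the grader
must judge the direction *perpendicular* to the RPE–choroid junction
(RPE-C) by eye, on an image whose axial and lateral micron-per-pixel
scales differ by a factor of ~3. Small angular errors and small lateral
landmark errors translate into thickness errors of tens of micrometres on
curved anatomy.

`choroidtrace` implements an automated alternative: each choroid boundary
— the lower surface of the RPE/Bruch's complex (RPE-C) and the
choroid–sclera interface (C-S) — is traced as the posterior mean of a
Gaussian process (GP) over lateral position, grown by a recursive Bayesian
scheme that scores candidate edge pixels by image-gradient evidence and
model fit. Measurements are then made in physical units, exactly
perpendicular to the fitted RPE-C, at fovea-referenced locations.

## The tracing model

A boundary is a function $r(x)$ giving sub-pixel image row at lateral
position $x$ (micrometres). We place a GP prior
$r \sim \mathcal{GP}(m, k)$ with a squared-exponential kernel

$$k(x, x') = \sigma_f^2 \exp\!\left(-\frac{(x - x')^2}{2\ell^2}\right),$$

and a prior mean $m(x)$ equal to the linear interpolant between the two
user-supplied endpoint pixels. Accepted edge pixels are treated as
observations with i.i.d. Gaussian noise of standard deviation
$\sigma_n$.

The recursion starts from the two endpoints (the method expects these to
be chosen manually; `suggest_endpoints()` is a convenience extension, not
part of the method). At each step the scheme:

1. fits the GP posterior to the accepted observations;
2. advances `batch_columns` unvisited columns inward from each end and
   computes the posterior mean $\mu_c$ and SD $s_c$ there;
3. in each column, collects candidate rows with nonzero edge-map support
   inside the credible band $\mu_c \pm \kappa \max(s_c, \sigma_n)$
   (`credible_multiplier` $\kappa$), and scores each candidate
   $$\text{score}(r) = w(g_r)^{\alpha} \,
     \exp\!\left(-\tfrac{(r-\mu_c)^2}{2\max(s_c,\sigma_n)^2}\right)^{1-\alpha},$$
   where $g_r$ is the gradient magnitude and $\alpha$ is `score_weight`;
4. accepts the best-scoring candidate per column as a new observation
   (ties broken toward the posterior mean, then the smaller row), skips
   columns without support, and refits.

The returned trace is the final posterior evaluated on every column of the
span, so occluded regions (vessel shadows) are interpolated by the kernel
and carry visibly inflated posterior SD. More than 50% of columns without
any candidate raises a low-evidence failure rather than a silent guess.

**The KDE evidence weight.** The role of the kernel density estimate in
the published pipeline schematic is not fully specified. Here the KDE is
fit to the nonzero gradient magnitudes of the edge map and its cumulative
distribution is used as the evidence weight $w(g)$: a pixel whose gradient
sits in the upper tail of the image's gradient distribution has weight
near 1. The cumulative form is a deliberate choice — the raw density is
not monotone in $g$, and the scoring contract requires that, at equal
distance from the posterior mean, the stronger gradient wins. The
geometric-mean combination zeroes the score whenever either evidence term
vanishes.

**Hyperparameters.** Defaults: $\ell$ = 500 µm (smooth anatomy, ~44
columns at Spectralis resolution), $\sigma_f^2$ = 2500 px²,
$\sigma_n$ = 4 px, $\kappa$ = 3, $\alpha$ = 0.5, batches of 15 columns.
$\sigma_n$ deserves a note: under multiplicative speckle the column-wise
gradient peak is mislocalized by a few pixels, and the candidate band is
floored at $\kappa\sigma_n$. With $\sigma_n$ = 1 px the band can exclude
the true edge once a few noisy observations are accepted, after which the
trace locks onto speckle and diverges; 4 px (~15 µm axially) keeps the
band honest about localization uncertainty while the posterior smooths the
jitter. Hyperparameters are held fixed during the recursion; whether the
original method refits them is unstated, and fixing them keeps the scheme
a standard GP.

## Preprocessing

The pipeline is median filter → contrast-limited adaptive histogram
equalization (CLAHE) → polarity-selected vertical derivative →
morphological opening plus small-component removal. The published account
names the stages but not their parameters; defaults (median window 5,
CLAHE clip limit 0.005 with an 8×8 tile grid, Gaussian pre-smoothing
σ = 2 px, horizontal 1×3 opening element, components under 5 px removed, a
support threshold at 5% of the maximum response) were tuned on synthetic
fixtures for sub-pixel localization of the C-S transition — they are
implementation choices, not published values. The RPE-C map uses
bright→dark axial polarity (bright RPE band above darker choroid), the C-S
map dark→bright (darker choroid above brighter sclera).

## Measurement geometry

All geometry is computed in micrometre space (`x = (col−1)·lateral_scale`,
`y = row·axial_scale`); angles computed in pixel space would be distorted
by the ~3:1 scale anisotropy. Perpendicular CT estimates the RPE-C tangent
by least squares over a ±50 µm window, casts the inward normal ray, and
intersects it with the piecewise-linear C-S curve. Parallel CT replays a
caliper's direction to mimic the manual measurement including its angular
error; on a flat choroid of thickness $t$ the two are related by the
secant law $t_\parallel = t/\cos\theta$, whose small-angle expansion
$t\theta^2/2$ is the quadratic error growth the evaluation reproduces.

Measurement locations are the fovea and ±2000 µm (temporal negative for a
right eye); offsets snap to the nearest column with exact half-pixel ties
moved toward the fovea, a documented deterministic rule. CA integrates the
*vertical* boundary separation over a ±3000 µm lateral strip — the
"3000-micron radius" of the macular protocol is read as a half-width of
the 6000 × 6000 µm ETDRS square restricted to one B-scan, because a
Euclidean radius mixing axial and lateral micrometres has no anatomical
meaning on a single cross-section. The trapezoidal rule is exact for the
piecewise-linear traces.

Indices are 1-based throughout (the R convention; the default fovea column
of a 768-wide scan is 384).

## The synthetic world

`generate_bscan()` renders layered retina / bright RPE band / choroid /
sclera intensities along configurable junction curves, with linear
blending at sub-pixel boundaries, dark elliptical vessels inside the
choroid, multiplicative gamma speckle (shape $1/s^2$, mean 1 — the
standard single-parameter OCT speckle approximation), attenuated shadow
column spans, and 8-bit quantization. Geometry defaults follow the
acquisition the method targets: 768×768 px covering 8.7 mm laterally
(11.33 µm/px); the axial scale is *not* published for these scans, so the
Spectralis-nominal 3.87 µm/px is used and remains configurable — every
physical result in this package depends on whatever axial scale the user
supplies. What the generator does **not** emulate: coherent A-scan
physics, realistic intraretinal layers, eye-motion artefacts, and real
C-S boundary diffuseness. A green tracer test therefore establishes
correct recovery of speckled, occluded, layered scenes with known truth —
not clinical-grade performance on pathology.

The simulated grader draws its angular error from
$\mathcal{N}(0.5°, 2.5°)$, the empirical distribution reported for a
trained human grader, applies it in micrometre space, and jitters the
lateral landmark. In the longitudinal cohort generator the manual-CT error
is the secant factor *plus* an additive landmark term (default SD 15 µm):
on a flat choroid the secant factor alone at 2.5° is sub-micrometre, far
smaller than any realistic automated residual, and the documented
mechanism — manual measurements noisier than automated ones — lives in the
interaction of angular/landmark error with curved, non-parallel real
anatomy that a per-scan scalar model cannot carry. This is the one place
the stated world adds a parameter beyond the published values, and it is
flagged accordingly.

Cohorts follow a living-donor transplant structure: donors and recipients
at weeks 0, 1, 4, 8, 12, 52; per-patient CT random intercepts (SD 40 µm
around 300 µm); linear CT ramps reaching the observed 1-year automated-CT
changes (+14.1% recipients, −4.9% donors — the donors' early transient
inflation is deliberately not modelled); visit daytime jitter of 1 h
around each patient's baseline. Renal markers are standardized linear
functions of standardized true CT (default slope +1 for eGFR, −1 for
creatinine and urea) and relative daytime (−0.4), plus a per-patient
random intercept and residual noise (both SD 0.5), mapped to clinical
units by fixed location/scale constants.

## Statistical conventions

* **Residuals** are automated − manual; positive means the automated
  measurement is larger. The published limits of agreement for this
  method are not symmetric about the published mean residual (they are
  symmetric about its negative), suggesting a flipped sign convention in
  the source's agreement plot; this package follows the text's definition
  and notes the discrepancy.
* **ICC** is Shrout–Fleiss ICC(3,1): two-way mixed effects, single rater,
  consistency — insensitive to a fixed inter-method shift.
* **Passing–Bablok** uses the original rank-based estimator (slopes of
  exactly −1 excluded, offset K counting slopes below −1) with the
  analytic rank-based confidence intervals. Exact scale-equivariance
  holds when no pairwise slope crosses −1 under the transformation.
* **Bland–Altman** limits are mean ± 1.96 SD with the n−1 denominator.
* **Major discrepancies** are residuals strictly exceeding 32 µm in
  absolute value, the published interobserver-variability bound.
* **Mixed models** are random-intercept fits by REML (`lme4`), with the
  response and continuous covariates z-scored on the analysis subset and
  sex centred — full standardization, consistent with near-zero published
  intercepts, though the source does not state explicitly that the
  response was standardized. Confidence intervals are Wald; conditional
  R² is the Nakagawa–Schielzeth variance partition
  $(\sigma_\text{fixed}^2 + \tau^2)/(\sigma_\text{fixed}^2 + \tau^2 +
  \sigma_e^2)$.
* **Standardized-slope recovery.** With a z-scored response, the
  estimand for the choroid term is the latent generating slope divided by
  the realized SD of the latent marker (which exceeds 1 whenever several
  effects plus noise contribute variance). `generate_cohort()` therefore
  stores both the latent slopes and the implied z-scale coefficients per
  replicate (`attr(tab, "truth")$beta_z`); recovery tests target the
  latter. A zero-noise cohort is recovered to machine precision with
  conditional R² = 1.

## Degenerate inputs and numerical choices

Duplicate observation columns raise a conditioning error (the GP adds a
1e−10 jitter but refuses genuinely singular designs). An all-identical
gradient sample degrades the KDE to a point mass with a warning. Traces
whose C-S crosses RPE-C are rejected at segmentation construction.
Zero-variance series make correlations an error, not an NA. A caliper
that never intersects the C-S curve inside the span is an error in the
metrics module and a flagged invalid row in the grader simulator.

## Known limitations

Single B-scan only (no volume tracing); fovea column is supplied
metadata, not detected; endpoints are inputs; no vascularity index; PNG/
TIFF readers are deliberately absent — images travel as plain-text PGM
(P2) with metadata in comment lines, which keeps the package text-only
and dependency-light. The donor cohort's non-monotone trajectory and any
imputation of missing clinical covariates are out of scope.
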