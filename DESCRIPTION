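Package: choroidtrace
Title: Gaussian-Process Edge Tracing and Longitudinal Analysis of the
    Choroid in EDI-OCT B-Scans
Version: 0.1.0
Authors@R:
    person("choroidtrace", "developers", email = "dev@choroidtrace.org",
           role = c("aut", "cre"))
Description: Automated measurement of choroidal thickness and area from
    enhanced depth imaging optical coherence tomography (EDI-OCT) B-scans.
    The choroid's two boundaries (the RPE-Bruch's complex lower surface and
    the choroid-sclera interface) are traced as Gaussian-process posteriors
    grown by a recursive Bayesian scheme that scores candidate edge pixels
    by image gradient evidence and model fit. Thickness is measured
    perpendicular to the upper boundary at fovea-referenced locations and
    area over the ETDRS macular window. Includes a synthetic B-scan, grader
    and cohort simulator with known ground truth, method-comparison
    statistics (Passing-Bablok, Bland-Altman, ICC(3,1)), and random-intercept
    mixed-effects modelling of choroid-renal-marker associations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
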