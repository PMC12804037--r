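---
title: "Automated tumor-stroma ratio quantification: methods and design"
author: "tsrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tumor-stroma ratio quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrquant)
```

## The problem

The tumor-stroma ratio (TSR) — the fraction of stromal area relative to
stroma plus epithelial tumor within a region of a histological section —
is a prognostic biomarker in colon cancer: stroma-rich tumors carry a
worse prognosis. Conventional scoring is visual, performed by a
pathologist on one microscope field, and carries interobserver
variability. `tsrquant` implements the downstream, fully automated half of
a digital-pathology TSR workflow: it consumes per-slide multi-class
tissue segmentation label masks (the output of a pixel-wise segmentation
model; producing those masks is out of scope here) and returns a
slide-level TSR, a stroma-high/low call, a data-driven cut-off, and
survival stratification for cohorts.

## The quantification model

A slide is represented as a `label_mask`: an integer raster of tissue
class codes with a physical resolution in microns per pixel (mpp). The
class vocabulary covers background plus ten tumor-associated classes
(tumor epithelium, tumor stroma, necrosis, mucin, smooth muscle, mucosa,
submucosa, adventitial tissue, dense lymphocytic infiltrates, bleeding
areas) and an `excluded` code for artifact pixels. The class map is
user-extensible — additional codes are treated as "other" tissue — since
segmentation vocabularies differ between models.

The engine processes the tumor region systematically:

1. **Artifact exclusion.** Pixels flagged by a binary artifact mask are
   relabeled to the `excluded` code before any analysis.
2. **Analysis region.** The bounding box of all tumor-epithelium pixels,
   dilated by one ROI radius and clipped to the mask.
3. **Sliding-window grid.** Circular ROIs of diameter 1 mm (default)
   slide across the region with 70% overlap, i.e. a stride of
   `(1 - 0.70) x diameter` = 300 px at mpp 1.0. Only discs lying fully
   inside the mask are candidates; scan order is row-major.
4. **Eligibility.** Each ROI must pass (i) a composition test — strictly
   less than 10% background (artifact pixels count as background), 20%
   necrotic debris and 30% mucin — and (ii) a four-quadrant test
   requiring tumor epithelium in all four axis-aligned quadrants of the
   disc.
5. **TSR and hotspot.** For each eligible ROI,
   `TSR = area_stroma / (area_stroma + area_tumor)`; all other classes
   are excluded from the formula. The slide-level TSR is the maximum over
   eligible ROIs (the stroma "hotspot"); a slide with no eligible ROI is
   reported as not assessable.
6. **Classification.** Stroma-high iff TSR percent strictly exceeds the
   cut-off (default 77; the visual-scoring convention uses 50 with the
   same strict rule).

### Geometry conventions

All coordinates are 0-based with pixel centers at integer positions,
x = column and y = row, including the GeoJSON overlays. Disc membership
is **strict** Euclidean distance `< diameter/2` from the ROI center; with
this rule a 1000-px disc has a maximal integer offset of 499 px, which
makes the admissible-center range and the sliding-window grid
well-defined without padding semantics at the mask border. Pixels exactly
on a quadrant dividing line belong to the right/lower quadrant. Physical
parameters are converted to pixels by `round(x / mpp)` with a floor of
1 px; the categorical mask itself is never resampled.

### Decisions where the design was open

* **Threshold strictness.** Content equal to a composition threshold is
  ineligible. The thresholds are stated as strict upper bounds on allowed
  content, and a strict rule gives an exact, testable boundary.
* **Artifact pixels in eligibility.** Excluded pixels count toward the
  effective background fraction and never enter the TSR numerator or
  denominator. Heavily artifacted ROIs therefore fail the composition
  test rather than contributing distorted ratios.
* **Quadrant test tissue.** Only tumor epithelium is counted (the TSR
  denominator tissue); the minimum per quadrant is a parameter
  (default 1 px) since "presence of tumor tissue" is not otherwise
  quantified.
* **Tie-break.** Equal hotspot TSRs resolve to the first ROI in row-major
  scan order, making results deterministic and byte-reproducible.

## Cut-off derivation

Two data-driven routes are implemented on cohort tables
(`id`, `tsr_percent`, `dfs_months`, `dfs_event`, `os_months`,
`os_event`, covariates):

* **Youden / ROC** (`youden_cutoff`): survival is binarized at a fixed
  horizon — default 36 months for disease-free survival (DFS), 60 months
  for overall survival (OS), matching the 3-year/5-year reporting
  convention — excluding patients censored before the horizon. Candidate
  thresholds are the unique observed scores, test-positive means
  `score > t`, and J = sensitivity + specificity − 1 is maximized with
  ties going to the smallest threshold. Time-dependent ROC would be the
  natural refinement; it is deliberately not implemented.
* **Log-rank scan** (`logrank_scan_cutoff`): thresholds on a 1% grid are
  scored by the two-group log-rank chi-square, discarding splits that
  leave either group below 10% of the cohort (a stability guard the
  maximally-selected-statistic literature requires). The maximal
  statistic is multiplicity-inflated; the result carries an explicit
  `multiplicity_warning` and the number of thresholds tested instead of a
  corrected p-value.

Survival machinery (Kaplan-Meier curves and horizon rates, log-rank test,
Cox proportional hazards with Breslow tie handling and Wald 95% CIs,
reversed-KM median follow-up, chi-square association tests) is delegated
to the `survival` package and base R behind the module's interface; the
scan's inner log-rank statistic is a vectorized in-package implementation
cross-checked against `survdiff` in the test suite.

## What the synthetic generators emulate

`simulate_mask` emulates the *structure* of segmentation output, not its
appearance: a smooth stroma-fraction field (low-resolution uniform noise,
bilinearly upscaled, bounded in [0.25, 0.60] by default), per-pixel
stroma/tumor draws from that field, pockets of necrosis, mucin and
background, artifact overlays, and one planted hotspot disc. The hotspot
is painted by deterministic dithering so its stroma:tumor pixel ratio
equals the target (0.80 by default) exactly up to one pixel — the
ground-truth hotspot TSR is therefore known by construction. Two sizing
choices make recovery well-posed: the field is capped strictly below the
hotspot target, so the hotspot is the unique maximum; and the default
hotspot diameter (1.5 mm) exceeds the ROI diameter plus the worst-case
grid offset at a 300-px stride, so at least one grid ROI always lies
fully inside the hotspot.

`simulate_cohort` emulates the statistical structure of a stage II/III
colon-cancer cohort: TSR from a truncated-normal mixture
`0.65 N(60, 14) + 0.35 N(84, 7)` (about 35% of patients above 77%,
mirroring the roughly 65/35 stroma-low/high split); DFS times exponential
with baseline rate `-log(0.82)/36` per month (82% 3-year event-free
survival in the low group) multiplied by a hazard ratio of 2.5 above the
true cut-off of 77% and by modest age (log-HR 0.02/year) and stage
(log-HR 0.5 for stage III) effects; administrative censoring at 72
months plus 30% uniform dropout; OS coupled to DFS so that a fraction of
DFS events are deaths (15%) or are followed by death after an
exponential lag (40%), guaranteeing OS times never precede DFS times.

What passing tests on these inputs do **not** show: robustness to
segmentation error modes (the generator plants clean class labels, not
misclassified boundaries), to stain or scanner variation (invisible at
the mask level), or to real lesion morphology (pockets are discs, fields
are smooth). Results on synthetic data validate the quantification and
statistical machinery, not the upstream segmentation.

## Numerical choices and degenerate inputs

* Compositions are exact pixel-count fractions; each ROI's fractions sum
  to 1 by construction.
* `compute_tsr` raises an error on a zero denominator; inside
  `quantify_slide` this cannot occur because the four-quadrant test
  guarantees tumor pixels.
* Cox fits use Breslow ties (`survival::coxph` defaults, tolerance
  1e-9); collinear designs and event-free cohorts raise errors rather
  than returning NAs.
* Reversed-KM median follow-up reports `reached = FALSE` with an open
  lower bound when more than half the cohort dies before censoring.
* All simulation randomness flows from a single integer seed; rerunning
  any generator or analysis with the same inputs is byte-identical.

## Problem sizes used in the shipped checks

The validation suite runs at desk scale, chosen to exercise every code
path with exact oracles: engine-vs-naive-reference equivalence on twenty
128–256 px masks with a 32-px ROI; hotspot recovery on fifty
2000x2000 px slides at mpp 1.0 with the 1-mm ROI; cut-off recovery on
one hundred cohorts of n = 1000; Cox CI coverage on two hundred cohorts
of n = 853 at a true HR of 1.67; log-rank type-I error on one thousand
null cohorts; and a 1.0/1.5/2.0-mm ROI sweep on ten slides at mpp 2.0.

## Known limitations

* Single slide per case; no multi-slide aggregation.
* No reading of proprietary whole-slide formats or image pyramids — the
  input is the flat label mask a segmentation backbone emits.
* The ROC binarization discards patients censored before the horizon,
  which loses information relative to time-dependent ROC.
* The log-rank scan reports an uncorrected maximum; treat its p-value as
  descriptive.
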