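# tsrquant

Fully automated **tumor–stroma ratio (TSR)** quantification from
multi-class tissue segmentation label masks, with data-driven cut-off
derivation and survival stratification.

## Who this is for

The TSR — the fraction of stroma relative to stroma plus epithelial tumor
in a region of an H&E section — is a prognostic biomarker in colon
cancer: stroma-rich (stroma-high) tumors have worse disease-free and
overall survival. `tsrquant` is for computational-pathology and
biostatistics groups who already run a pixel-wise tissue segmentation
model over whole-slide images and need the downstream, human-free half of
the workflow: turning per-slide class masks into a slide-level TSR and a
stroma-high/low call, deriving the optimal cut-off on a cohort, and
running the stratified survival analyses.

## The method

Given a label mask (integer raster of tissue classes, with
microns-per-pixel metadata) and an optional binary artifact mask:

1. Artifact pixels are relabeled to an `excluded` class.
2. The tumor analysis region is the bounding box of tumor-epithelium
   pixels dilated by one ROI radius.
3. A circular ROI (default diameter 1 mm) slides over the region with
   70% overlap (stride = 0.3 × diameter).
4. Each ROI must pass two eligibility tests:
   composition — strictly `<10%` background (artifact counts as
   background), `<20%` necrotic debris, `<30%` mucin — and the
   four-quadrant test — tumor epithelium present in all four quadrants
   of the disc.
5. Per eligible ROI, `TSR = area_stroma / (area_stroma + area_tumor)`;
   the slide-level TSR is the **hotspot**: the maximum over eligible
   ROIs. Slides with no eligible ROI are "not assessable".
6. The slide is stroma-high iff `TSR% > cutoff` (default 77; the visual
   convention uses 50).

Cohort-level tooling derives the cut-off two ways — Youden index on ROC
with survival binarized at a horizon (36 months DFS / 60 months OS), and
a maximally discriminative log-rank scan over a 1% grid with a 10%
minimum group size — and runs Kaplan–Meier/log-rank/Cox (Breslow ties)
stratification, reversed-KM median follow-up, and chi-square association
tests. Synthetic generators (`simulate_mask`, `simulate_cohort`) produce
masks with an exactly known hotspot TSR and cohorts with a known
threshold effect, so the whole pipeline is testable end to end without
slide data.

## Worked example

```r
library(tsrquant)

# a synthetic slide with a planted hotspot of known TSR
s <- simulate_mask(width = 2000, height = 2000, mpp = 1.0, seed = 7)
s$truth$hotspot$tsr
#> [1] 0.7999998

q <- quantify_slide(s$mask, s$artifacts, roi_params(diameter_um = 1000))
q$result
#> <slide_result 'sim_7': TSR 80.0% (stroma_high), 16/16 ROIs eligible>
```

The engine recovered the planted 80% hotspot: of the 16 candidate ROI
positions all passed both eligibility tests, and the maximal (hotspot)
ROI reads 80.0% — above the 77% cut-off, hence `stroma_high`.

```r
# a synthetic cohort with a true threshold effect at 77%
sim <- simulate_cohort(n = 1000, seed = 7)
b <- binarize_at_horizon(sim$cohort, "dfs", 36)
youden_cutoff(b$scores, b$outcomes, 36)
#> <cutoff_result youden: cutoff 76.96%, criterion 0.3251>
logrank_scan_cutoff(sim$cohort, "dfs")
#> <cutoff_result logrank_scan: cutoff 77%, criterion 113.6>

rep <- run_study(sim$cohort, endpoint = "dfs", cutoff_percent = 77)
c(rep$horizon_survival, hr = rep$cox_univariate$hr)
#> $stroma_low  [1] 0.7984
#> $stroma_high [1] 0.5059
#> $hr          [1] 2.685
```

Both cut-off methods land within a tenth of a point of the true 77%
threshold; at the fixed 77% cut-off the stroma-high group shows markedly
worse 3-year disease-free survival (51% vs 80%) and a Cox hazard ratio
above 2, as planted by the generator.

A command-line dispatcher is installed at
`system.file("cli/tsrquant.R", package = "tsrquant")` with subcommands
`quantify`, `batch`, `cutoff`, `survival`, `simulate` and `roi-sweep`
(the last compares 1.0/1.5/2.0-mm ROI sizes per slide).

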