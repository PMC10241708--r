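# vesselquant

Digital image analysis of tumor vasculature on CD34 / α-SMA dual-stained
brightfield sections, with downstream survival statistics.

In many solid tumors — breast cancer in particular — the size of tumor
vessels, not just their number, carries prognostic information: a large
median vessel calibre has been associated with shorter disease-specific
survival. Quantifying that reproducibly requires an automated pipeline:
separating the two chromogens, segmenting vessels despite broken or
incomplete wall staining, measuring a size statistic robust to oblique
sectioning, scoring pericyte coverage around each vessel, pooling replicate
tissue-microarray (TMA) cores into case-level metrics, and testing the
association with outcome. vesselquant implements that pipeline for
pathologists and computational biologists working with pre-extracted
core/ROI images, plus a synthetic-data module so every stage can be
validated against known ground truth without patient data.

## Method

- **Optical density & deconvolution.** Per channel, `OD = log10(255 / I)`
  (Beer–Lambert; intensity 255 = no staining, OD clamped at `I = 1`). The
  pixel OD 3-vector is unmixed by least squares onto unit stain colour
  vectors `V_s` (defaults: fast red for the CD34 chromogen, fast blue for
  α-SMA; both config-overridable), giving per-stain OD amount maps; the
  CD34 map becomes a 256-grade layer.
- **Segmentation.** Threshold (Otsu or fixed) → binary median despeckle
  (disc r = 2 px) → repair: dilate (r = 3 px), fill holes, binary
  mean + median smoothing (r = 2 px), erode back → 8-connected labeling →
  size filter at a 4 µm minimal-Feret floor (excludes single CD34+ cells).
- **Morphometry.** Per vessel: minimal Feret diameter (rotating calipers on
  the pixel-corner hull — the minimal distance between two parallel
  tangents). Per image: vessel density (vessels/mm²), perivascular α-SMA
  intensity PVI (median OD in the Euclidean 10-px band around vessels),
  fraction of covered vessels FCV (perivascular OD above a cohort-median
  cutoff), stromal area and stromal α-SMA OD.
- **Aggregation.** TMA cores of a case pooled as one tissue (or
  median-of-cores); inter-core concordance via one-way random-effects
  ICC(1,1) with F-based CI.
- **Statistics.** Median dichotomization ("low (0–50%)" vs "high (> 50%)",
  ties low), Spearman correlations, Mann–Whitney / Kruskal–Wallis tests,
  Kaplan–Meier + log-rank, univariable / multivariable cause-specific Cox
  models (Breslow ties; Wald CIs and p values), and per-subgroup forest
  tables.

All pixel-based defaults assume the 4 px/µm scanning convention.

## Worked example

Render a synthetic dual-stained field with known ground truth, measure it,
and fit the survival stage on a simulated cohort:

```r
library(vesselquant)

lay <- generate_vessel_layout(6, sma_covered_fraction = 0.5, seed = 42)
ren <- render_ihc_image(lay, noise_sd_od = 0.02, seed = 43)
m <- measure_image(ren$image)
m$metrics
#>  n_vessels density median_diameter_um    pvi fcv stromal_area_mm2 stromal_od
#>          6   366.2              17.18 0.1074  NA        0.0003244     0.8486
```

All 6 vessels are recovered; detected minimal Feret diameters (µm) track
the generator's truth within a fraction of a pixel:

```r
round(sort(ren$truth$diameter_um), 2)   # 11.52 12.89 16.16 17.93 19.11 24.34
round(sort(m$per_vessel$min_feret_um), 2)  # 11.50 13.08 16.36 18.00 19.00 24.50
```

The per-vessel perivascular ODs separate covered from uncovered vessels
(≈ 0.84 vs ≈ 0.09 here), which is what FCV dichotomizes at cohort level.
Downstream, a simulated 300-case cohort with a true hazard ratio of 3 for
the high-vessel-size group is recovered by the dichotomize → Cox stage:

```r
co <- generate_cohort(300, true_log_hr = log(3), censoring_rate = 0.3, seed = 7)
cox_fit(co$time, co$event, data.frame(size_group = dichotomize(co$size_um)))
#> Cox proportional-hazards fit (breslow ties), n = 300, events = 210
#>             term   coef    HR ci_low ci_high     se        p
#> 1 size_grouphigh 1.1415 3.131  2.333   4.203 0.1502 2.92e-14
```

`run_pipeline(default_run_config(seed = 1))` chains every stage
(synthesize → separate → segment → measure → aggregate → associate) and
writes per-vessel/per-image/per-case CSVs, KM coordinates, a statistics
JSON and a run manifest; `inst/scripts/vesselquant` is a thin command-line
wrapper (`vesselquant all --config run.yaml`). See the vignette
(`vignettes/vessel-morphometry.Rmd`) for the model, parameter rationale and
the generator's scope.

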