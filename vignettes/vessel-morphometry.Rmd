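---
title: "Vessel morphometry and perivascular scoring on dual-stained histology"
author: "vesselquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel morphometry and perivascular scoring on dual-stained histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## The measurement problem

Tumor sections dual-stained for CD34 (an endothelial marker, here a red
chromogen) and alpha-smooth-muscle actin (a-SMA, a pericyte/smooth-muscle
marker, here a blue chromogen) carry three kinds of vascular information:
how many vessels there are, how large they are, and whether they are
invested by a-SMA-positive mural cells. vesselquant turns an 8-bit RGB
image of such a section into per-vessel, per-image and per-case metrics,
and links the case metrics to survival. The pipeline is:

1. **Stain separation.** Pixel intensity relates to chromogen amount
   through the Beer-Lambert law, so each channel is converted to optical
   density, `OD = log10(255 / I)`, which is linear in stain amount;
   intensity 255 is the complete absence of staining. The 3-vector of
   channel ODs at each pixel is then unmixed by least squares onto unit
   stain colour vectors, giving one OD amount map per chromogen. The CD34
   map is requantized to a 256-grade layer for segmentation.
2. **Vessel segmentation.** The CD34 layer is thresholded (fixed value or
   Otsu), despeckled with a binary median filter (disc radius 2 px), and
   repaired: dilate, fill enclosed holes, binary mean then median smoothing
   (radius 2 px), erode back. The repair step turns incompletely stained
   walls — C-shaped rings with gaps, objects with holes — into solid
   vessel cross-sections. Components are labeled with 8-connectivity and
   filtered by a minimal-Feret floor of 4 um, which doubles as the rule
   that excludes single CD34+ cells.
3. **Morphometry.** Vessel size is the minimal Feret diameter (the minimal
   distance between two parallel tangents), computed by rotating calipers
   on the convex hull of pixel corner points; it is robust to elongation
   from non-tangential sectioning. Vessel density is vessels per mm^2 of
   analysed tissue. The perivascular space of each vessel is the Euclidean
   band within 10 px of its footprint, excluding all vessel pixels, with
   contested pixels assigned to the nearer vessel (ties to the lower
   label). PVI is the median a-SMA OD over ring pixels; FCV is the
   fraction of vessels whose perivascular OD exceeds a cutoff; stromal
   metrics summarize marker-defined stroma outside vessels.
4. **Case aggregation.** Replicate TMA cores of one case are pooled as one
   tissue sample (vessel tables concatenated, areas summed) by default; a
   median-of-cores mode is available because both conventions are
   defensible readings of core-to-case summarization. Inter-core
   concordance is quantified with a one-way random-effects ICC(1,1).
5. **Cohort statistics.** Metrics are dichotomized at the cohort median
   (ties low), compared across clinical groups with rank tests, and
   related to disease-specific survival with Kaplan-Meier/log-rank and
   cause-specific Cox proportional-hazards models (Breslow ties by
   default), univariable, multivariable, and per-subgroup (forest table).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `resolution_px_per_um` | 4 | px/um | the scanning convention all pixel-based defaults assume |
| `i_floor` | 1 | intensity | caps OD at log10(255) ~ 2.41, keeping OD finite and order-preserving at I = 0 |
| stain vectors | fast red / fast blue presets | unit OD vectors | the chromogens' published colour-deconvolution presets; batch-specific vectors should override them in config |
| `od_max` | 2.0 | OD | 256-grade quantization scale; covers realistic chromogen densities |
| `threshold` | `"otsu"` | grade 0-255 | visual threshold selection is not reproducible; Otsu is recorded in provenance, a fixed integer is accepted |
| `despeckle_radius_px` | 2 | px | removes speckle noise and nonspecific staining |
| `enlarge_radius_px` | 3 | px (0.75 um) | closes staining breaks up to ~6 px (sub-cell width); exposed because no authoritative value exists |
| `smooth_radius_px` | 2 | px | mean/median smoothing of the repaired outline |
| `min_feret_floor_um` | 4 | um | the caliper width of the smallest retained vessels, consistent with capillary calibre after fixation shrinkage |
| `ring_distance_px` | 10 | px (2.5 um) | perivascular band width, defined in pixels at the stated resolution |
| `stroma_threshold_od` | 0.15 | OD | marker-positive stroma definition; config-exposed, no authoritative value |
| FCV cutoff | cohort median of per-vessel perivascular OD | OD | a per-case median would force FCV toward 0.5 for every case and carry no information; the cohort-level cutoff makes FCV discriminative between cases. A per-case convention remains available |

Binary "mean" and "median" filters coincide on binary images when the mean
is followed by a majority (> 0.5) rule; both are implemented as a majority
vote over the disc, with replicated borders so constant masks are fixed
points. Hole filling floods from the image border, so holes touching the
border are not filled. "Covered" uses a strict inequality (ties count as
uncovered). Dichotomization sends ties at the median to the low group,
matching the "low (0-50%)" / "high (> 50%)" interval labels.

## The synthetic-data generator

No patient images or outcomes ship with the package; the generator
provides ground truth for every stage instead.

**Images.** Vessels are elliptical annuli: an open lumen, an endothelial
wall 1.5-3 um thick carrying the CD34 chromogen (OD amount 1.0), and —
for the covered fraction — an a-SMA ring (width 2 um, OD 0.8 for covered
vs 0.05 for uncovered) just outside the wall, over a uniform low-OD
stroma (0.05). Lumen minor-axis diameters are log-normal (strictly
positive and right-skewed, like real vessel calibres) floored at 4 um;
eccentricity up to 0.6; a configurable fraction of walls carries a gap of
up to 4 px (the "C-shape" the repair stage must close). Sub-resolution
CD34+ distractor dots (1.5-3 um) exercise the size filter. Footprints are
placed without overlap, with clearance so that morphological closing
cannot merge neighbours. Rendering is the forward Beer-Lambert model:
channel intensity `round(255 * 10^-(sum_s A_s * V_s[c]))`, clipped to
0-255; Gaussian noise of a chosen sd is applied in OD-amount space, and
the *realized* amount maps are returned as the unmixing ground truth. The
per-vessel truth table reports the outer minor-axis diameter
(lumen + 2 x wall): the minimal Feret diameter of the filled object that
segmentation reconstructs.

What the generator does *not* emulate: scanner optics, focus artifacts,
tissue folds, fat or necrosis (beyond a binary exclusion mask),
CD34+ fibroblast-like staining, or spatially correlated stain variation.
Passing recovery tests therefore demonstrates the correctness of the
algorithms on well-posed scenes, not robustness to every histological
artifact; on real slides the QC/exclusion flags and the configurable
thresholds carry that burden.

**Cohorts.** Per-case vessel median size is log-normal (median 12 um, log
sd 0.35). Cases above the cohort median size form the high group, whose
event hazard is `baseline_hazard * exp(true_log_hr)` under an exponential
baseline (0.004 events/month, i.e. median survival around 14 years,
consistent with a screening-detected series) — the simplest generator
consistent with proportional hazards, with closed-form truth. Independent
exponential censoring is calibrated by root-finding so the expected
censored fraction equals the requested rate. Clinical covariates (age,
tumour size, grade, nodal status, ER/PR/HER2) are drawn with
screening-cohort-like frequencies, independent of vessel size, matching
the absence of metric-clinicopathology associations in the motivating
setting.

## Numerical choices and degenerate inputs

- **Minimal Feret.** The minimum caliper width of a convex set is attained
  flush against a hull edge, so the implementation takes the convex hull
  of the pixel corner points and minimizes the point-line distance over
  edges. A single pixel has width 1 px; an empty footprint is an error.
  Projection width is piecewise linear (kinked) at its minimum, so
  validation sweeps evaluate hull-edge normals as well as a uniform
  3600-angle grid.
- **Unmixing** is ordinary least squares with negative amounts clipped to
  zero (full NNLS available via config when pracma is installed);
  rank-deficient stain matrices are an error, not a warning.
- **Otsu** on the 256-grade layer converts the continuous threshold to the
  smallest integer t with `layer >= t` equivalent for integer data, and
  records it in the mask provenance.
- **Empty results** (no vessels, no stroma pixels, empty rings, no events,
  a single group) yield NA-flagged metrics with warnings, never silent
  zeros and never crashes; Cox non-convergence and monotone likelihoods
  raise explicit errors.
- **Determinism.** Every random draw descends from the run seed through
  fixed arithmetic; identical config + seed reproduce output files byte
  for byte. When a heavy-tailed case calibre cannot fit the requested
  vessel count on one core, synthesis retries deterministically over
  sub-seeds and then sheds vessels (large vessels <-> fewer per field, as
  in tissue) before giving up.
- **ICC** uses Searle's unbalanced one-way formulas; the 95% CI comes from
  the F distribution of MSB/MSW. The estimator's sampling sd at 300 cases
  x 3 cores is ~0.03, so recovery checks average 10 replicate simulations
  of that design.

## Validation suite sizes

The test suite regenerates all fixtures in code at these scales, chosen to
finish comfortably on one CPU: 200 shapes for the Feret oracle (120 unit
point clouds, 80 rasters), 50 rendered fields for the deconvolution round
trip, 20 seeded 512 x 512 px images (8 vessels, 15 distractors each) for
segmentation recovery, 1000 null cohorts of n = 300 plus 20 effect
cohorts of n = 500 for survival calibration, and 10 x 3 ICC simulations at
300 cases x 3 cores. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## A worked single-image run

```{r example}
lay <- generate_vessel_layout(6, sma_covered_fraction = 0.5, seed = 42)
ren <- render_ihc_image(lay, noise_sd_od = 0.02, seed = 43)
m <- measure_image(ren$image)
m$metrics
head(m$per_vessel)
```

The detected vessel count and diameters can be compared directly with
`ren$truth`, which is how the recovery tests are built.

## Known limitations

- Stain vectors are configuration, not estimated from the image; badly
  mismatched vectors degrade separation silently (the residual is not
  currently scored).
- The 10-px perivascular band is resolution-dependent by construction;
  at resolutions other than 4 px/um, set it from a physical distance.
- Whole-slide pyramid formats are out of scope; inputs are pre-extracted
  core/ROI rasters.
- Vessel-shape complexity (fractality, lacunarity), proliferating-vessel
  indices and competing-risks models beyond cause-specific coding are not
  implemented.
- The synthetic cohort ties survival to vessel size through a single
  dichotomous proportional-hazards effect; it is a calibration instrument,
  not a disease model.
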