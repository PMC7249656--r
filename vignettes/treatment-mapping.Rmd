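---
title: "Mapping forest fuel treatments from paired-year imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest fuel treatments from paired-year imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Forest fuel treatments — clearcuts, thinnings and prescribed fires — leave a
spectral imprint on multiband satellite imagery: cutting removes canopy and
drops near-infrared (NIR) reflectance while exposing soil (raising Red and
shortwave-infrared, SWIR), and burning depresses the normalized burn ratio.
Treatment records, however, are scattered across ownerships and lag years
behind. `treatscan` turns a pair of co-registered, same-grid images from two
consecutive years into a map of likely treatment units, with an audit trail
for every polygon it accepts or rejects.

The pipeline, run end to end by `run_pipeline()`:

1. **Radiometric harmonization** (`histogram_match`): the later image is
   matched band-by-band to the earlier one through binned empirical CDFs, so
   inter-annual differences in sun angle or atmosphere do not masquerade as
   change. A coarser SWIR band can be aligned to the base grid with
   `upsample_bilinear` (exact for linear fields, cell-center aligned,
   edge-clamped).
2. **Change features** (`compose_predictors`): a principal-component
   transform is fitted to each year's four 10 m bands separately (SVD of the
   centered pixel matrix, all components kept). Matching components by index
   gives two change metrics per component: the difference, post minus pre,
   and the ratio, pre over post (the two orientations are deliberate and
   kept as defined; the ratio uses a `1e-9` guard and emits nodata at
   near-zero denominators). Each metric is summarized by 3x3 focal mean and
   focal standard deviation (population denominator, the GIS convention;
   edge cells use the neighbors that exist). Two spectral indices complete
   the stack: the relativized burn ratio
   `RBR = (NBR_pre - NBR_post) / (NBR_pre + 1.001)`, which stays
   informative where pre-fire vegetation is sparse, and post-year
   `NDVI = (NIR - Red) / (NIR + Red)`. The result is an 18-band stack in a
   fixed rank order: focal means of the difference metric first, then its
   focal STDs, then the ratio metric's means and STDs, then RBR and NDVI.
3. **Correlation pruning** (`prune_correlated`): among all mutually finite
   pixels, any band pair with `|r| > 0.75` loses its lower-priority member
   (larger rank number), visiting pairs in rank order. In practice most of
   the ratio-metric bands are dropped as redundant with the difference
   metric; RBR and NDVI survive.
4. **Training** (`draw_candidate_points`, `label_points`,
   `balance_training`, `extract_predictors`): 500 points are placed
   uniformly at random on forest cells, labeled by point-in-polygon against
   known mechanical-treatment units, and the sample is topped up with
   points placed inside those units until treatments make up 30% (+/- 2
   percentage points) of the set — treatments are rare on a landscape, and
   an unconstrained sample would contain almost none. Points snap to cell
   centers so predictor extraction is exact rather than interpolated.
   Non-treatment points are never deleted. (The alternative of relocating
   existing points instead of adding new ones would shrink the background
   sample; adding preserves it.)
5. **Classification** (`fit_random_forest`, `predict_vote_raster`): a
   100-tree Random Forest in which each tree trains on an independent 66%
   subsample drawn *without* replacement — a fixed-ratio subsample, not a
   bootstrap — with `floor(sqrt(p))` candidate predictors per split. The
   remaining 34% per tree form its out-of-bag (OOB) set. Three OOB metrics
   are reported, built from each sample's OOB vote share of its correct
   class `q_i`: RMSE `sqrt(mean((1 - q_i)^2))`, average relative error
   `mean(1 - q_i)`, and the relative classification error (share of
   samples with `q_i < 0.5`; a tied vote counts as an error for the
   treatment class, the conservative reading). Prediction writes a two-band
   vote raster — per cell, the fraction of trees voting non-treatment and
   treatment — which sums to one everywhere finite.
6. **Segmentation** (`mean_shift_segment`): the treatment-vote band is
   smoothed by flat-kernel mean-shift filtering in the joint spatial-range
   domain and cut into 8-connected segments of similar filtered value;
   segments below 10 cells merge into the neighbor with the closest mean
   vote. Detail parameters follow the familiar 1-20 scale (higher = finer):
   spatial detail `d_s` maps to a kernel diameter of `21 - d_s` cells and
   spectral detail `d_r` to a range bandwidth of `(21 - d_r)/20` of the
   band's value range. The defaults — spectral 20, spatial 10 — favor
   spectral discrimination at moderate spatial smoothing.
7. **Polygons** (`threshold_polygonize`, `filter_polygons`): cells whose
   segment-mean vote exceeds a threshold become polygons (8-connected cell
   squares, holes preserved, areas exact). `suggest_threshold` proposes the
   5th percentile of segment values inside known treatment units. Three
   rules then prune false positives, in order: polygons under 1 ha are
   slivers; polygons intersecting a wildfire perimeter of the period —
   boundary touches count — are wildfire artifacts; polygons with more than
   half their area over non-forest cells are agricultural or other
   non-forest change (a deterministic surrogate for manual photo
   interpretation). An optional user-supplied exclusion layer (clouds,
   haze, snow) removes with reason `"user"`. Nothing is discarded silently:
   the audit set plus the survivors always reassemble the candidates.
8. **Prescribed fire** (`merge_burned`, `prescribed_fire_polygons`):
   per-date binary burned-area rasters are OR-merged, polygonized and passed
   through the same filter ledger, so burns inside known wildfire perimeters
   drop out and the survivors are labeled prescribed fire.
9. **Assessment** (`sample_validation`, `contingency`, `accuracy_report`,
   `roc_auc`): an independent stratified sample — 500 cells inside
   treatment polygons, 500 outside — is compared against the vote raster
   binarized at 0.25, 0.5 and 0.75 ("greater than" is strict). Each
   threshold yields a 2x2 error matrix with overall accuracy and its
   binomial standard error, user and producer accuracies per class, and the
   uncorrected chi-square statistic
   `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom (no
   continuity correction — this is the form whose values match standard
   accuracy-assessment reports). The ROC curve sweeps every distinct vote
   value, grouping ties, and integrates AUC by trapezoid — identical to the
   Mann-Whitney statistic with ties counted one half.
10. **Density** (`kernel_density`): treatment polygons are rasterized to
    100 m cells, treated cells become points, and a quartic (biweight)
    kernel with a 1 km radius yields treatments per square kilometer; the
    kernel integrates to one per point, so total mass equals the point
    count.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| correlation threshold | 0.75 | \|r\| | above this, bands are interchangeable for the forest and slow it down |
| training points | 500 / 30% | points / fraction | enough backgrounds to span the landscape; enough treatments to split on |
| trees / train ratio | 100 / 0.66 | — | vote resolution of 1%; each tree sees two thirds of the data, leaving a third for honest OOB error |
| mtry | floor(sqrt(p)) | predictors | the standard decorrelation rule |
| spectral / spatial detail | 20 / 10 | 1-20 scale | finest spectral splitting at moderate spatial smoothing |
| minimum segment | 10 | cells | 0.1 ha at 10 m — below it, vote noise masquerades as units |
| sliver threshold | 1 | ha | management units smaller than 1 ha are not mapped |
| binarization thresholds | 0.25 / 0.5 / 0.75 | vote share | a lenient, a majority and a strict reading of the votes |
| density cell / radius | 100 / 1000 | m | neighborhood scale of treatment clustering |

All of these surface in `pipeline_defaults()` and are overridable per run.

## What the synthetic scenes emulate — and what they do not

`scene_spec()` / `generate_scene()` produce the paired-year scenes the test
suite and the acceptance script run on. The reference conditions are a
240 x 240-cell scene at 10 m (576 ha), 85% forest, five clearcuts (effect
0.5: post-year NIR times 0.5, Red and SWIR raised accordingly), five
thinnings (effect 0.2), two prescribed fires and one wildfire (NIR down,
SWIR up, so NBR drops), an agricultural green-to-plowed patch outside the
forest mask and a shadow patch (all bands scaled down, which leaves ratio
indices unchanged — exactly why such confusers are hard). Footprints are
random ellipses of at least 2 ha, mutually disjoint with a 2-cell buffer.

Three generator choices are deliberate realism, not convenience:

* **Treatments are rare.** Disturbed footprints cover about 6% of the
  scene. Histogram matching maps quantiles, so any change that moves a
  large share of the distribution would be partially "corrected away";
  keeping treatments rare is both what real landscapes look like and the
  regime in which quantile matching is safe.
* **Bands co-vary.** A persistent multiplicative brightness field (10%
  coefficient of variation, shared by all bands and both years) gives the
  rank-one inter-band covariance structure of real vegetation imagery.
  This is what makes a per-image PCA stable: with independent equal-variance
  bands the principal directions would be arbitrary rotations and
  cross-year component matching by index would be meaningless.
* **Noise scales with reflectance.** Per-band, per-year autocorrelated
  noise (Gaussian-filtered, scale 3 cells) has standard deviation
  `noise_sd x (band mean / NIR mean)`, anchoring `noise_sd = 0.03` to the
  brightest band. Uniform absolute noise would put over half the visible
  bands' signal into noise and destroy the index information no real sensor
  loses.

What the scenes do **not** emulate: topographic shading, phenology between
acquisition dates, cloud and cirrus contamination, sensor resampling
artifacts, mixed-severity burns, or sub-pixel misregistration. Passing the
suite therefore demonstrates that the pipeline recovers treatments whose
spectral contrast stands clear of autocorrelated radiometric noise — it does
not certify performance on imagery whose artifacts fall outside this list,
and the visual-labeling steps of an operational workflow (assigning
clearcut vs thinning, vetting haze) remain with the analyst.

A note on reproducibility: scenes draw from R's default Mersenne-Twister
stream, seeded once, in a fixed order — brightness field, per-band pre-year
noise, per-band post-year noise, then footprints (clearcuts, thinnings,
prescribed fires, wildfires, confusers). Effects are applied outside the
stream, so raising an effect size changes no placement, and adding
confusers never moves a treatment.

## Numerical choices and degenerate inputs

* Histogram matching uses 1024 equal-width bins over the joint source and
  reference range; the inverse CDF uses the infimum convention, skipping
  empty-bin runs. Quantization error is one bin width where distributions
  are dense and bounded by the local reference sample spacing in sparse
  tails. Constant bands are returned unchanged with a warning.
* PCA loading columns are sign-fixed (largest-magnitude entry positive) so
  SVD sign indeterminacy cannot flip a change metric between runs.
* Mean-shift filtering is the blurring variant: at most 100 iterations or a
  maximum shift below `1e-4` of the value range. Component labeling uses an
  absolute tolerance floor of `1e-9` so a constant surface stays one
  segment despite last-ulp float differences.
* Ties: a cell exactly at a binarization or polygonization threshold stays
  0 (rules are strict `>`); a tied ensemble vote classifies non-treatment.
* Geometry: cell (1,1) is the top-left cell; a value represents the cell's
  full square footprint; polygonization traces directed boundary edges with
  the interior on the left, so outer rings are counterclockwise, holes
  clockwise, and signed ring areas sum exactly to cell count times cell
  area. Rasterization tests cell centers (even-odd rule), making
  polygonize-then-rasterize an exact inverse. All pipelines require a
  projected CRS in meters; geographic (degree) grids are rejected because
  the hectare rules would be meaningless.
* Nodata is `NA` in memory and a sentinel (default -9999) on disk; any
  operation consuming nodata emits nodata, and statistics ignore it.

## Problem sizes

The shipped test-and-acceptance configuration uses the 240 x 240 reference
scene (57,600 cells) for the end-to-end runs and 120 x 120 scenes for
module-level tests; a full pipeline pass takes roughly half a minute on one
core. These sizes were chosen so that treated area stays a realistic small
fraction of the landscape while every footprint still spans hundreds of
cells; nothing in the implementation is specific to them, and desk-scale
scenes of a few thousand hectares run comfortably.

## File formats

Rasters are uncompressed float64 GeoTIFFs (band-sequential, one strip per
band, georeferencing in standard GeoTIFF tags, band names and nodata in an
embedded JSON description) written and read by `write_raster` /
`read_raster`. Polygon sets exchange as GeoJSON FeatureCollections
(`write_polygons` / `read_polygons`) with MultiPolygon nesting and hole
assignment. These are deliberately plain, widely readable formats; GDAL
and friends open both.

## Known limitations

* Component matching across years is by index; if a real image pair's
  second and third components swap roles (e.g. under heavy smoke), the
  difference metrics for those components blur. The focal statistics and
  the index bands are unaffected, and the forest can down-weight the
  damaged bands, but the effect is untested here.
* The ratio change metric is numerically wild wherever a post-year
  component score passes near zero; it is retained for fidelity to the
  metric's definition, guarded to nodata at `|denominator| < 1e-9`, and in
  practice mostly pruned away by the correlation rule.
* The OOB error-metric formulas are one consistent reading of their
  one-line definitions (vote share of the correct class); other readings
  (e.g. squared-error on probabilities per class) would differ in the
  second decimal on typical runs.
* `filter_polygons` rasterizes each candidate onto the full grid for the
  non-forest rule; for scenes far beyond desk scale this is the first thing
  to optimize.
* Mean-shift bandwidths follow a fixed, documented mapping from the 1-20
  detail scale; other tools' internal mappings are proprietary, so
  cross-tool comparisons should be made at the property level (segment
  counts, minimum sizes), never cell by cell.
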