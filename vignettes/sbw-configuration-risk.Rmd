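---
title: "Landscape configuration and spruce budworm infestation risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape configuration and spruce budworm infestation risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sbwrisk)
```

## The problem

Eastern spruce budworm (*Choristoneura fumiferana*) is the dominant
defoliator of fir–spruce forests in eastern North America. Beyond stand-level
host availability, the *spatial configuration* of conifer forest — how large,
connected and regularly shaped its patches are — is hypothesised to modulate
where moderate-to-severe defoliation establishes: fragmented conifer mosaics
concentrate dispersing adults on limited resources. `sbwrisk` implements a
spatially explicit pipeline that quantifies this relationship and estimates,
tile by tile and year by year, the likelihood that a landscape configuration
resembles configurations that experienced defoliation.

The chain is: multiband reflectance → stand segmentation → configuration
metrics on a 400 m tessellation → rule-based disturbed/undisturbed labelling
→ random-forest likelihood models with temporal cross-validation, ROC
thresholding, permutation importance and partial dependence. Because the
satellite and aerial-survey inputs of a real deployment are large and
proprietary in scale, the package ships a first-class synthetic landscape
generator that reproduces the statistical structure the analysis assumes, so
that every downstream stage is testable and the whole chain can be validated
by parameter recovery.

## The synthetic landscape generator

`generator_config()` collects every knob; `generate_landscape()` runs the
three stages under seeds derived from one integer, so identical
configurations are byte-identical.

**Land cover.** A neutral-landscape model: Gaussian white noise is smoothed
by FFT (toroidal boundary, which keeps the field stationary) and thresholded
at the conifer quantile. The smoothing radius interpolates *geometrically*
between 0.3 of the grid edge (fragmentation 0: a few grid-scale blocks) and
half a cell (fragmentation 1: speckle). Geometric interpolation matters: a
linear map leaves mid-range fragmentation far coarser than the 400 m
analysis grain, so tiles degenerate to solid conifer squares and every
configuration metric collapses to a constant.

The conifer class is deliberately a *two-component* mosaic: a coarse matrix
plus, in proportion to fragmentation, a fine-grained component of scattered
conifer whose local intensity is modulated by an independent coarse field
(scattered remnant and regenerating conifer clusters regionally rather than
raining down uniformly). With a single thresholded field, mean patch area,
largest patch index and cohesion are rank-copies of one local-density factor
(Spearman correlations ≈ 0.99), and no analysis could attribute an effect to
one of them rather than another. The second component lets largest-patch
dominance vary between tiles of equal conifer density, which is what makes
the generative coefficients identifiable — and is also closer to real boreal
mosaics, which carry structure at more than one scale. Non-conifer cells are
split by a second rough field into mixedwood (45%), hardwood (30%),
shrub/barren (15%) and water (10%). The default fragmentation of 0.7 was
calibrated so the tile-level metric distributions match the ranges the
analysis is designed for: largest patch index straddling 50%, mean shape
index reaching 1.35, fewer than 5% of tiles saturated at LPI = 100.

**Severity process.** The infestation unit is the 400 m tile. For every tile
with conifer, the six metrics are computed, standardised across tiles
(population z-scores), and combined as

log-odds(infestation | exposed) = `risk_intercept` + `effect_beta` · z.

A front enters from the south (`front_start`, default 0.85 of the grid
height) and advances north (`front_speed`, default 0.03 per year); exposed,
conifer-modal, not-yet-infested tiles are infected by a Bernoulli draw each
year, and infected tiles persist (recovery is available via
`recovery_prob`, default 0). Infected tiles are rasterised by assigning
moderate/severe severity (2 or 3) to their forested cells; exposed but
uninfested tiles carry scattered light defoliation. The high default
exposure encodes that the generated domain stands for the *active* region an
annual survey radius selects — the samples the models ever see — with a
residual northward advance retained. Defaults for the effect
(`LPI = -1`, `PA = -0.5` per standard deviation, intercept −1.5) encode the
fragmentation hypothesis at a per-year onset hazard of ≈ 0.18 for an average
exposed tile.

**Reflectance.** Band means are conditioned on cover and severity in scaled
surface-reflectance units (reflectance × 10 000, the convention of
distributed Landsat products — also the scale on which the segmentation
threshold below is meaningful): defoliated conifer brightens in red and SWIR
(browning, loss of foliage water) and darkens in NIR, proportionally to
severity class and the host content of the cover; water keeps a fixed
signature. Gaussian noise (default sd 80) is added. No quantitative spectral
deltas are published for severity classes; the magnitudes (red +60, NIR
−140, SWIR +110 per class for conifer) are free parameters chosen to give
class contrasts comparable to between-cover contrasts.

**What the generator does not emulate:** radiative transfer, budworm
population dynamics (phenology, parasitoids, dispersal kernels), annual
land-cover change, geolocation error in sketch-mapped severity polygons, or
the spatial autocorrelation of real defoliation *within* the exposed zone.
Passing recovery tests therefore shows the analysis chain is sound, not that
real Landsat/survey data would yield the same numbers.

## Stand segmentation

`segment_stands()` performs iterative pairwise region merging from
single-cell seeds. The cost of merging 4-adjacent regions is

f = (1 − shape) · Δh_colour + shape · Δh_shape,

where Δh_colour is the growth in size-weighted per-band population standard
deviation, and Δh_shape mixes a compactness term `n·p/√n` and a smoothness
term `n·p/b` (p = region perimeter in cell sides, b = bounding-box
perimeter) with the compactness weight. Merges execute while `f < scale²`
(defaults: scale 50, shape 0.3, compactness 0.5), using local
mutual-best-fitting with a fixed ascending-label scan and lower-label tie
breaks, so runs are deterministic; the merge order of the commercial
implementation this emulates is unpublished, so boundary-level equivalence
with it is not claimed. Region adjacency is 4-neighbour so that perimeters
are well defined; the 8-neighbour rule is reserved for patch delineation in
the metrics. Post-processing merges stands under 0.45 ha into the neighbour
with the longest shared boundary (iteratively; isolated remnants become
nodata) and assigns each stand the modal land cover, ties resolving
conifer > mixedwood > hardwood > shrub > water.

## Configuration metrics

Patches are maximal 8-connected components of the conifer class inside an
analysis window; perimeters count 4-neighbour cell sides exposed to other
classes, nodata, or the window boundary, so every tile is a self-contained
landscape (deterministic and comparable across tiles). The six metrics:

* **PA** — mean patch area (ha);
* **LPI** — percent of the window's unmasked area in the largest patch;
* **COHESION** — `100·[1 − Σp/Σ(p√n)]/[1 − 1/√Z]`, Z = unmasked cells;
* **LSI** — total class edge over the minimum possible edge for the class
  area (class form: 1 for one maximally compact patch);
* **AREA_CV** — coefficient of variation of patch area, reported as a
  percentage with the population standard deviation (a CV is dimensionless;
  it is sometimes tabulated with area units, which we treat as a label
  artefact);
* **SHAPE** — mean over patches of perimeter over the minimum perimeter for
  the patch's cell count, with the minimum-perimeter function
  `4m`, `4m+2`, `4m+4` for `m = ⌊√n⌋` (verified against exhaustive
  polyomino enumeration in the tests).

All six are computed for conifer only — the analysis contrasts conifer
configurations, and computing the two landscape-level metrics over all
classes would mix host and non-host geometry; a window without conifer
yields defined missing values, never silent zeros. An independent
brute-force implementation (igraph component labelling plus direct formula
evaluation) is kept in the test suite and must agree to 1e-9 relative
tolerance on hundreds of random windows.

## Tessellation and labelling

A 400 m (16 ha) tessellation is imposed with cells joining the tile that
contains their centre (400 m is not a multiple of the 30 m grain; centre
membership is deterministic and area-preserving in expectation). Cells are
masked when water, burned in or before the year, or harvested within 15
years before the series start. Per tile-year, the disturbed fraction is the
share of *unmasked* area (masked cells carry no evidence) under moderate or
severe defoliation: ≥ 50% → disturbed, < 25% → undisturbed, between →
excluded. Light defoliation does not count toward that fraction but does
count as disturbance for the undisturbed minimum-mapping-unit test: an
undisturbed tile must contain a contiguous 1 ha extent of unmasked,
severity-0 cells. Tiles whose modal unmasked cover is not conifer are set
aside (`non_conifer`) so the undisturbed class is never populated by mere
host absence.

**Onset protocol.** The models estimate the probability of infestation
*onset*: `filter_onset()` lets a tile contribute a disturbed sample only in
its first disturbed year and excludes it from both classes afterwards. This
is not cosmetic. Defoliation persists and a tile's configuration fingerprint
is nearly static, so without the filter an expanding-window model scores
recurring tiles by *recognition*: in a control experiment with all
configuration effects set to zero, the pooled temporal-CV AUC was 0.86
purely from memorisation, versus 0.50 with the filter. It is also the
protocol implied by an undisturbed definition that excludes any tile with
disturbance history.

## Likelihood models

Features are the six metrics at three scales — the focal tile and the merged
3×3 (144 ha) and 5×5 (400 ha) windows (computed on the merged regions, not
averaged over member tiles; edge tiles with incomplete rings are dropped) —
weighted 1 / 0.4 / 0.2 and robust-scaled (median centred, divided by the
5–95 quantile range). Scaling statistics are estimated on training data only
and applied to test data; a global mode is available for compatibility with
workflows that scale once. Samples are restricted annually to tiles inside
the search circle (area-weighted centroid of the disturbance polygons;
radius to the maximum-northing vertex of the northernmost polygon of at
least 5 ha, plus a 75 km dispersal extension) and balanced per year by
undersampling the majority class.

Two regimes, both probability forests with 100 trees, minimum leaf 9,
maximum depth 10, and all features available at each split:

* `fit_full_series()` — expanding-window temporal CV: the fold for year *y*
  trains on all years before *y*; pooled out-of-fold probabilities give the
  overall ROC, AUC and the threshold maximising TPR − FPR (ties to the
  highest cutoff). A final all-data refit backs prediction and partial
  dependence.
* `fit_annual()` — stratified 5-fold CV within one year.

**Permutation importance** is the decrease in the *pooled* out-of-fold
accuracy (0.5 cutoff) when one feature is shuffled within each fold's test
data; the distribution is over 100 shuffles. Measuring on held-out folds
keeps memorised features from registering; pooling before the accuracy
comparison keeps per-fold chance skill — which shuffling cannot remove fold
by fold — from inflating every feature. Two standard errors are reported:
the Monte-Carlo SE over shuffles, and the test-set sampling SE of the
accuracy difference (`se_sampling`). Whether an importance is
distinguishable from zero is a question about the population decrease, so it
is judged against `se_sampling`; the Monte-Carlo SE shrinks without bound as
shuffles are added and would eventually flag any infinitesimal realised
bias.

**Partial dependence** clamps a feature to 20 evenly spaced quantiles of its
training values between the 5th and 95th percentile — the same robust band
the scaling uses; clamping every sample to a value observed almost nowhere
is extrapolation, not dependence — and averages the predicted probability
over all samples. Passing a metric name (e.g. `"LPI"`) clamps its three
scale copies at rank-matched quantiles, tracing the dependence on the metric
itself. When judging monotonicity of a curve, rises below 0.01 predicted
probability are treated as flat: a bagged ensemble of 100 votes produces
sub-percent step artefacts at split boundaries at any sample size, and
counting those as trend violations would make monotonicity unattainable for
any finite forest (`pd_increase_count()` exposes the tolerance).

## Validation studies and problem sizes

`recovery_study()` runs the full chain on a landscape with known effects
(`LPI −1`, `PA −0.5` per standard deviation). The canonical size is a 45×45
tile tessellation (600×600 cells of 30 m, 18 km edge) over eight annual
steps, chosen to put roughly two thousand tiles under analysis while keeping
a study under a few minutes on one core. At seed 1 the fitted model ranks an
LPI feature first by permutation importance and its LPI partial dependence
falls monotonically (no rise above the 0.01 tolerance beyond the allowance),
and the null configuration (`effect_beta = 0`) yields pooled AUC ≈ 0.50
with all importances within two sampling SEs of zero.

One number deserves honesty rather than a pass: the pooled temporal-CV AUC
of the recovery study is ≈ 0.71. Under the onset protocol the label is a
single Bernoulli draw per tile at the stated effect sizes, and the
*Bayes-optimal* pooled AUC — computable directly from the generative
logistic with annual depletion of susceptible tiles — is ≈ 0.77. No fitted
model can exceed that bound; abandoning the onset protocol raises the
apparent AUC to ≈ 0.92 but only by re-admitting the recognition leakage that
the null control exposes. We keep the valid protocol and report the bound.
It is worth noting that ≈ 0.71 is essentially the discrimination reported
for this class of model on real data.

## Numerical choices and degenerate inputs

Seeds fan out from one integer (land cover `s`, severity `s+1`, reflectance
`s+3`; balancing `s+11`, model fits `s+13`, importance `s+17`), all within
32-bit range. Constant features (zero 5–95 range) are dropped with a
warning. Years without both classes contribute no fold; a run with no
modellable year returns a manifest with status `"no-model"` rather than an
error; a fully masked tile is `masked`; a window without conifer yields NA
metrics. Misaligned rasters fail hard with grid diagnostics. All tabular
outputs are CSV, rasters are ESRI ASCII grids and tile grids GeoJSON — plain
text formats any GIS reads — and every output file is checksummed in the run
manifest (`run_pipeline()` reruns are byte-identical).

## Known limitations

Segmentation boundaries are not claimed to match any commercial tool;
annual land cover is static within a run; the severity process has no
within-zone spatial contagion beyond the front; species composition and
climate are out of scope by design; and the search-circle geometry cannot
emulate survey-frontier selection on a compressed synthetic domain, which is
why exposure is a generator parameter instead.
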