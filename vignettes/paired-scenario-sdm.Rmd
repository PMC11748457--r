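---
title: "Paired-scenario ensemble SDMs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-scenario ensemble SDMs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedSDM)
```

## The problem

*Sphenomorphus incognitus* is a small forest skink of southern China,
tied to moist, sloped, wooded habitat. Its range sits in one of the
most intensively developed regions on Earth, so two questions matter
for its conservation: how much of its climatically suitable habitat is
actually available once human land use is accounted for, and does a
model that knows about land use describe the species' occurrences
better than one that does not?

pairedSDM frames this as a paired-scenario experiment. Scenario 1
("natural") models occurrence probability from climate and terrain
only; scenario 2 ("disturbance") adds a categorical land-use layer.
Both scenarios share the same occurrences, pseudo-absences and
train/validation splits, so every difference between the two habitat
maps is attributable to the land-use information.

## Workflow and model

1. **Thinning.** Occurrences are thinned so no two retained points lie
   within a minimum great-circle distance, curbing spatial
   autocorrelation. The filter is a greedy pass over a
   seeded random ordering; the visiting order is stored so a run can
   be audited.
2. **Collinearity filtering.** Continuous predictors are kept greedily
   in a priority order, each accepted only if its absolute Pearson
   correlation with every already-kept predictor is ≤ 0.8 (0.9 in the
   pairing experiment, which deliberately re-admits more collinear
   factor combinations). Categorical layers are never tested.
3. **Pseudo-absences.** 500 background cells drawn uniformly over the
   non-missing domain, optionally outside an exclusion buffer around
   presences (default 0 km — the source analysis states none).
4. **Registry fits.** Nine learner families, each reduced to a
   probability predictor: logistic regression (GLM), decision tree
   (CTA), bagged trees (RF), two gradient-boosted configurations (GBM:
   eta 0.1/depth 3/100 rounds; XGBOOST: eta 0.3/depth 6/60 rounds), a
   single-hidden-layer network (ANN, 5 units, decay 0.01), linear
   discriminant on a linear+quadratic basis (FDA), a penalized
   adaptive-spline surface (MARS, per-variable smooths, k = 5), and an
   L1-regularized logistic model on linear+quadratic+hinge features
   (MAXENT, knots at the quartiles, penalty chosen by seeded 5-fold
   CV). Hyperparameters are pinned, not tuned, mirroring a
   default-settings platform run. Fits that error or collapse to
   constant output are flagged failed and kept in the bookkeeping but
   excluded from ensembles.
5. **Evaluation and the composite score.** Validation-split
   predictions are binarized at the TSS-maximizing threshold (scanned
   over all midpoints between sorted unique scores, ties toward the
   smaller threshold); TSS, kappa and CSI come from that confusion
   table, AUC from midrank Mann–Whitney statistics. The composite
   score multiplies each of CSI/kappa/AUC/TSS by 0.5 if it exceeds its
   quality threshold (0.3/0.4/0.9/0.7) and by 0.3 otherwise, then
   divides by 4. The conditional weight punishes models with any
   sub-par metric; the score is monotone in every metric and bounded
   by 0.5.
6. **Ensembles.** Survivors are ranked by TSS (with a TSS ≥ 0.7
   eligibility gate) and by AUC (no gate — consistent with published
   shortlists that include sub-gate TSS models in the AUC block); the
   top five are combined by unweighted mean probability and
   re-evaluated. The better-evaluating committee draws the maps.
7. **Habitat grading and accounting.** Suitability maps are cut into
   four grades (unsuitable/poorly/moderately/highly) at Fisher–Jenks
   natural breaks, computed by the exact O(kn²) dynamic program on the
   sorted cell values. Areas are counted per grade in 10⁴ km² with a
   constant cell area (a spherical cell-area correction is
   deliberately omitted, matching the source accounting); scenario and
   period contrasts report the per-class and total deltas and the
   percentage change relative to the earlier map. The suitable-habitat
   centroid is the unweighted mean of suitable cell centers
   (suitability-weighted variant available), with displacement given
   as haversine distance and initial bearing.
8. **Pairing rubric and G-test.** Per validation point, five ordered
   rules compare the two maps (suitable-only-in-one; grade
   difference; equal grade with fragmentation; equal otherwise).
   Fragmentation is operationalized — the source leaves it
   qualitative — as *patch-count increase* (8-connected components of
   suitable cells within the buffer) *and* a suitable-fraction drop of
   at least 0.10, so uniform shrinkage without break-up never counts.
   Tallies across repetitions form the repetitions × {control, test}
   table tested by the likelihood-ratio G-test without continuity or
   Williams correction (the df = 9 published result identifies this
   10×2 reading; equality points stay out of the table).

## The synthetic study system

No original rasters ship with the package; a seeded generator emulates
their statistical structure:

- **Climate analogues** (19 layers) are smoothed Gaussian noise
  (radius 5 cells) with several pairs given correlations of 0.85–0.97,
  reproducing bioclim-style redundancy; correlations are imposed
  exactly in the empirical sense by orthogonalized mixing.
- **Terrain** comes from a smooth synthetic DEM via Horn's 8-neighbour
  gradients (slope, aspect with a −1 flat sentinel, hillshade at the
  cartographic default sun of azimuth 315°, altitude 45°).
- **Land use** cuts one smoothed field at quantiles, giving contiguous
  patches with shares woodland 0.45, shrub 0.10, grassland 0.10,
  cropland 0.20, urban 0.10, water 0.05.
- **The virtual species** follows a logistic niche in the
  precipitation analogue (`bio12`) and terrain slope (linear +5/+3 and
  quadratic −0.5 on z-scored layers, intercept −7), with suitability
  forced to zero on cropland and urban cells — the ground-truth
  disturbance effect. These effect sizes place the system in the
  discrimination regime of the real analysis (single-model AUC
  ≈ 0.9–0.97, suitable fraction of the landscape small); they were set
  from the generator's own Bayes-optimal AUC ceiling (≈ 0.96).

**Scale.** The default landscape is 100 × 100 cells of 1 km — the
real study spans a ~3000-km continental window at the same 1-km
resolution, so distance-based parameters are rescaled to the domain:
thinning 3 km (for 30 km) and rubric buffer 25 km (for 50 km). With 82
raw virtual presences this yields ~30–60 thinned records, matching the
82 → 62 retention of the real dataset in spirit. The 75:25 pairing
split supports `forced_counts` so printed 45/17-style counts can be
pinned exactly when fractions alone cannot round to them.

What the generator does *not* emulate: climate physics and seasonality
(layers are statistically, not physically, coupled), anisotropic
terrain, realistic land-use geography, observation bias in
occurrences, and spatial sampling artefacts. Passing recovery tests
therefore show the *pipeline* recovers known structure under its
assumptions — not that any particular real-world inference is correct.

## Numerical choices

- Exact Fisher–Jenks is quadratic in the sample; breaks are computed
  on at most 10⁴ sorted values (every m-th value beyond that), which
  classifies the default grids exactly and keeps a classification
  around a second.
- Great-circle math uses the haversine with Earth radius 6371.0088 km
  throughout (the source used projected Euclidean tools; differences
  at ≤ 50 km are negligible). Grid cells are georeferenced by a fixed
  km→degree conversion at the origin latitude.
- Threshold ties go to the smaller threshold; Jenks boundary values
  classify downward (a cell equal to a break stays in the lower
  grade); the flat-aspect sentinel −1 is excluded from any statistic.
- All generators and samplers are pure functions of their arguments
  including the seed; the pipeline derives per-stage seeds
  deterministically from one master seed and logs them.

## Open design points, resolved

- *Pseudo-absence redraw:* redrawn per repetition by default (a flag
  fixes them), since repetition-to-repetition variation is the point
  of the 10-run design.
- *Jenks breaks across maps:* computed per map by default (the
  published per-period areas indicate per-map breaks); a shared-breaks
  flag exists for strict cross-map comparability.
- *AUC-ranked ensembles:* no TSS floor (the published AUC shortlist
  contains a TSS 0.563 model), while TSS/γ-ranked selection gates at
  0.7.
- *Fragmentation sub-score:* the published tally's fragmentation
  column exceeds the test column in one repetition, so it cannot be a
  strict per-repetition subset of test points; this package counts
  fragmentation-credited test points (rule 4), which is a subset by
  construction, and reports the published column as-is in its bundled
  table.

## Limitations

Learner internals are not replicas of any specific modelling platform,
so single-model numbers are comparable in distribution, not one to
one. The rubric's fragmentation margin (0.10) is a declared
operationalization of an undefined published criterion; results near
the margin should be read with that in mind. Desk-scale simulations
use a small landscape; the test suite's problem sizes (grids of
40–100 cells a side, 5–10 seeds) were chosen as the smallest that
exercise every code path with stable statistics.
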