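---
title: "Methods: preliminary threat assessment from herbarium records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preliminary threat assessment from herbarium records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most plant species have never been assessed for the IUCN Red List, while
herbaria hold centuries of occurrence evidence for nearly all of them. A
practical response is *triage*: cheap, automatable classifiers that sort
species into "threatened" (CR, EN, VU) and "not threatened" (NT, LC) so
that scarce assessor time is spent where it matters. `herbassess`
implements five such classifiers, the range metrics beneath them, an
evaluation layer, and a Bayesian machinery for deciding whether one
classifier really outperforms another — plus a synthetic herbarium-data
generator with known ground truth, so the entire pipeline is testable
without any external data.

## Range metrics

**EOO** (extent of occurrence) is the area of the minimum convex polygon
around a species' georeferenced records; **AOO** (area of occupancy) is
the summed area of occupied 2 × 2 km grid cells; the **location count** is
approximated by occupied cells of a coarser (default 10 km) grid. These
are the quantities IUCN criterion B bands on: EOO thresholds 100 / 5 000 /
20 000 km² and AOO thresholds 10 / 500 / 2 000 km² for CR / EN / VU, with
location counts 1 / 5 / 10.

Two structural facts about specimen-derived metrics matter for
interpretation and are asserted by the test suite:

* AOO is bounded by 4 km² per specimen, so at least 500 specimens are
  needed before AOO can reach the 2 000 km² threatened-band threshold —
  herbarium AOO is almost always an underestimate.
* EOO of fewer than three distinct, non-collinear points is zero.

**Projection.** All areas are computed after projecting lon/lat to planar
kilometres with a Lambert azimuthal equal-area projection on the authalic
sphere, centred on the point centroid. Equal-area is the property the
metrics need; centring keeps shape distortion negligible over a species
range, which we verified by comparison against ellipsoidal geodesic
polygon areas (worst disagreement 0.65 % over 300 random ranges up to
~1 800 km across, |lat| ≤ 55°). We initially considered a cylindrical
equal-area projection with a centred meridian, but measured chord-versus-
geodesic area disagreements up to ~6 % at mid-latitudes, so the azimuthal
form — which is also what EOO-calculator tools in this field use — was
adopted. `compute_eoo()`/`compute_aoo()` recentre the projection on each
point set; an optional fixed centre (`lon0`, `lat0`) is available for
comparisons across changing point sets, since recentring can perturb EOO
at the ~10⁻⁶ relative level and invalidate strict monotonicity.

**Grid anchoring.** The occupancy grids are anchored so the projection
centre falls at a *cell centre*. Anchoring at the raw origin would put the
data centroid on a cell corner, splitting every tight cluster across up to
four cells. The anchor offset is exposed (`origin`) so users can probe
origin sensitivity; across quarter-cell shifts counts vary by at most a
factor of two.

## The classifiers

* **`classify_rcat()`** — EOO-only banding: CR < 100 ≤ EN < 5 000 ≤ VU <
  20 000 ≤ LC (km²). Comparisons are strict `<` against band upper bounds
  (the "less than X" phrasing of criterion B), so a species exactly on a
  threshold falls in the less-threatened band; a zero-area (point-like)
  range with at least one georeferenced record is CR; a species with no
  coordinates is unassessable (`NA`) and excluded from this method's
  denominators. NT is never emitted — EOO alone cannot separate NT from
  LC. An optional `use_aoo` mode also bands on AOO and takes the more
  threatened band.
* **`classify_conr()`** — criterion-B approximation under an assumed
  continuing decline: band X requires (EOO or AOO below X's range
  threshold) *and* location count ≤ X's location threshold; highest
  qualifying band wins; range-qualified species with too many locations
  become NT; species beyond both VU range thresholds are LC.
* **`classify_us_method()`** — a three-step triage tree over raw specimen
  evidence (no coordinates needed): no collection in the last 50 years
  before the reference year → Potentially Extinct; fewer than 5 specimens
  → Potentially Threatened; fewer than 3 distinct localities →
  Potentially Threatened; otherwise Not Threatened. All four numbers are
  parameters (`us_method_params()`): published calibrations of this tree
  vary by flora, so the *structure*, not the defaults, is the contract.
  The exit step of each species is recorded, so pathway proportions can be
  tabulated. Species with no usable collection year fail the recency check
  — absence of dated evidence is treated as absence of recent evidence.
  The ordering of the recency and count checks is switchable.
* **`classify_specimen_count()`** — threatened iff specimen count is
  strictly below a threshold; `select_count_threshold()` chooses the
  threshold maximizing whole-dataset accuracy (ties to the smallest
  threshold, full accuracy curve returned).
* **Random forest** (`rf_model` functions) — a supervised protocol: 75/25
  stratified split, hyperparameters tuned by 10-fold × 5-repeat
  cross-validation on ROC area over a small documented grid (500 trees,
  `mtry` ∈ {2, 4, 8}, node size ∈ {1, 5}), evaluation on the untouched
  test quarter, and predictor importance as mean decrease in out-of-bag
  accuracy under predictor permutation, computed directly from the kept
  in-bag matrix. Categorical predictors use target-agnostic integer codes;
  missing numerics are median-imputed with medians learned inside each
  training fold, so no information leaks from held-out data.

## Evaluation and comparison

Predictions are scored against reference categories binarized as CR/EN/VU
= threatened, NT/LC = not threatened (EX/EW/DD/NE are a hard error — they
must be filtered before evaluation). Per approach and stratum the report
carries confusion counts, accuracy, sensitivity, specificity and the
*default accuracy* — the accuracy of always predicting the majority
status, the baseline every method must beat. Methods are scored on the
species they can assess, so denominators legitimately differ. Per-category
accuracies (weighted by counts they average exactly to overall accuracy)
and correct-classification proportions by cited Red List criterion (A–D,
overlapping groups) are also produced.

Differences are judged by conjugate Bayesian estimation: accuracy uses a
binomial likelihood with a flat Beta(1, 1) prior (posterior
Beta(correct+1, n−correct+1)); sensitivity/specificity use a multinomial
likelihood over the four confusion cells with a flat Dirichlet(1,1,1,1)
prior, draws transformed to the two ratios. 10 000 exact posterior draws
per side are differenced and summarized by the central 95 % credible
interval; a difference is *significant* when zero lies outside it. Two
caveats are deliberate and documented: approaches are modelled as
independent even when evaluated on overlapping species, and no multiple-
comparison correction is applied. Under equal true proportions the rule
fires ~5 % of the time (checked by simulation, 500 replicates).

## The synthetic generator

`simulate_dataset()` emulates the structure of a large multi-group
herbarium validation set: 1 311 species in five groups of 105 / 837 / 97 /
176 / 96, true range extents log-uniform on [1, 10⁶] km² (straddling every
criterion-B threshold), specimen counts negative-binomial with mean
2.5 + 2·extent^0.20 (dispersion 8), collection years 1880–2015 with an
exponentially-tailed last-collection year so a realistic minority of
species look "lost", 10 % of records without coordinates (locality code
retained), 2 % cultivated and 2 % out-of-range flagged records, 5 % exact
duplicates, and an 8 × 8 lattice of admin units over a 40° × 40° window as
the locality layer. Reference categories come from the EOO band of the
*true* extent; with probability 0.2 a species' category is replaced by a
random one — the stand-in for assessments resting on non-range criteria.
Range-driven threatened labels cite criterion B (with D/A/C co-cited at
0.30/0.06/0.06); flipped threatened labels cite among A/C/D. This yields
the qualitative real-data pattern in which range-based classifiers do
better on criterion-B-citing species.

Two generator choices deserve explanation:

* **Rim anchors.** Up to eight specimen points per species are placed near
  the range rim (the rest uniform in the range disc, all with ~0.25 km
  jitter). Herbarium holdings accumulate over a century and typically span
  a species' range limits; statistically, the anchors keep the convex hull
  of sparsely collected species representative of the extent the label is
  based on. Without them the EOO of any 1–3-record wide-ranging species is
  near zero and no count distribution with realistic sparse species could
  pass label recovery.
* **Count–extent link.** The slope/exponent were calibrated once, during
  generator design, to two targets: the whole-dataset optimal count
  threshold lands in the 5–20 range (measured 17–19 across seeds),
  qualitatively matching published calibrations of the specimen-count
  rule, while EOO-band label recovery off threshold boundaries stays ≥
  0.98. A side effect is that per-species counts top out around ~120
  rather than the thousands seen for the most-collected real species;
  group-level specimen totals remain realistic.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: collector itineraries and spatial sampling
bias, georeferencing error structure, taxonomic mis-determination,
non-convex or fragmented ranges, and real climatic/socio-economic
predictor surfaces (the non-range predictors are weakly informative noise
fields, with a mild `min_hpd` signal so importance rankings have a
credible runner-up). Real-data performance claims require real data.

## Numerical choices

* Distinct-point test for hull degeneracy: exact equality after rounding
  projected coordinates to 1 mm; hull areas below 10⁻⁹ km² count as zero.
* Point-in-polygon: even-odd ray casting with an explicit on-segment test;
  boundary points belong to the first matching unit in the layer's stable
  order (determinism over geometric pedantry). Verified against an
  independent winding-number oracle.
* Antimeridian spanners: a species is excluded when its longitudes include
  values in (150°, 180°] and [−180°, −150°) — a blunt sentinel test, with
  the band configurable.
* Duplicate key: (species, longitude, latitude, collection year) with
  coordinates rounded to 4 decimal places (~11 m), configurable.
* Degenerate CV folds (single-class training part) are resampled with a
  warning; single-class held-out folds contribute no AUC and are dropped
  from the fold mean.
* All randomness flows from a single integer seed per run; pipeline
  reruns with the same configuration are file-identical.

## Problem sizes

The default end-to-end run — 1 311 species, ~25 000 records, all five
classifiers, the full 10 × 5 × 6-point forest tuning at 500 trees, and
10 000-draw comparisons — completes in under four minutes on one CPU; the
test suite, including the end-to-end and oracle-comparison blocks, runs in
about six. These sizes were chosen so a complete replication is an
interactive-scale exercise.

## Known limitations

* The location estimate is a fixed-grid proxy; true IUCN locations are
  defined by threatening events, which no coordinate-only method can see.
* The criterion-B approximation assumes continuing decline for every
  species; where that assumption fails it over-assigns threat.
* EOO-based banding never emits NT, so NT reference species are
  structurally misclassified by it (they binarize to not-threatened and
  the classifier can only produce LC on that side — the binary evaluation
  is unaffected).
* The Bayesian layer's independence assumption makes comparisons on
  overlapping species sets conservative in neither direction; a paired
  per-species model would be sharper and is left as an extension.
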