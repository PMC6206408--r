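---
title: "Detecting and counting sorghum heads: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting sorghum heads: models, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headcount)
```

## The problem

Fertile head (panicle) number per unit area is a yield component that
breeders and agronomists want per plot, across trials of hundreds to
thousands of plots. Aerial RGB imagery at sub-centimeter ground sampling
distance (GSD) makes heads visible, but a breeding trial is close to a
worst case for generic object detectors: genotypes differ in head color
(white, green, orange, brown), size and shape (main-stem vs tiller heads,
overlapping clusters), illumination changes within a single flight, and
the background mixes soil, shadow, dead leaves and green leaves.

`headcount` implements a deliberately simple two-stage pipeline: a
per-pixel scene classifier whose head classes are merged into candidate
regions, then a per-region count classifier. The stages are exposed as two
classic model-fitting functions, `dtsm()` and `head_count_model()`, each
returning an S3 object with `print`/`summary`/`predict` methods; the
surrounding steps (I/O, region morphology, evaluation, plot extraction,
simulation) are plain functions.

## Stage 1: decision-tree pixel segmentation (DTSM)

Each pixel is mapped to nine color features: normalized r, g, b; hexcone
H, S, V (H circular on [0, 1)); and CIE L\*a\*b\* computed with the
standard sRGB linearization, the published sRGB→XYZ matrix, and the D65
white taken as the matrix image of RGB (1, 1, 1) so that gray pixels are
exactly neutral. Only color is used — no texture — which keeps
classification a cheap per-pixel table lookup through a tree. A
consistent per-feature scale is documented rather than essential: a
decision tree is invariant to monotone per-feature rescaling, but models
are only portable between implementations that agree on the scale.

`dtsm()` fits a CART tree (via rpart) with Gini impurity. Unstated
hyper-parameters are exposed with defaults chosen for a 7-class problem
on ~10⁴ training pixels: `max_depth = 12`, `min_leaf = 5`, complexity
`cp = 1e-6` (effectively grow-to-limits). Leaf-majority ties break toward
the lowest class code, making predictions deterministic. Per-class
training pixels are sampled with a cap (`max_per_class`, default 2000 per
image) so abundant background classes cannot dominate; sampling is
seed-reproducible.

No pixel-level cleanup is applied between classification and region
extraction; small false components are removed by the region-level
minimum-area filter instead.

## Stage 2: region morphology and the quadratic-SVM counter

Candidate head regions are 8-connected components of the head mask
(8-connectivity because heads are blobby and anti-aliased edges would
fragment under 4-connectivity) with at least `min_area = 20` pixels —
about 0.4 cm² at 0.45 cm GSD, smaller than any real head.

Eleven features describe each region. Three conventions are worth
stating, because counting models do not transfer across conventions (the
convention tag is stored in fitted models, and `predict` refuses
mismatches):

* **Perimeter** is the number of region pixels with at least one
  non-region 4-neighbor — a boundary-pixel count, not a weighted contour
  length estimate.
* **Ellipse axes** come from the normalized second central moments with a
  +1/12 per-pixel variance correction, so a single pixel has finite axes
  (4·√(1/12) ≈ 1.155) and eccentricity 0.
* **Roundness** is 4π · filled area / perimeter², clipped to 1 (the
  boundary-count perimeter makes small discs exceed 1 otherwise);
  **convex area** counts pixel centers inside or on the convex hull of
  the region's pixel centers, and "extent" divides by the region's own
  bounding box.

`head_count_model()` labels each region with the number of hand-labeled
head centers its pixel set contains (0 = false detection; a point on a
boundary pixel is inside, since membership is per pixel) and fits a
one-vs-one multi-class SVM with a quadratic kernel, `(1 + γ·u·v)²`, via
e1071/libsvm. Features are z-scored with training statistics (quadratic
kernels are scale-sensitive); the box constraint defaults to C = 1 and
γ = 1/11. Count classes are capped at 5 — pooled "5+" — because regions
with more heads are rare and the class set must stay populated.
Cross-validated accuracy is computed with fold-internal standardization
(no leakage; the fold assignment is stored so tests can re-derive it).
Regions predicted 0 are retained, flagged, and contribute nothing to
image totals.

## Evaluation protocol

TP and FN are counted over labeled points, FP over detected regions
containing no point. This asymmetric convention is the only one under
which TP + FN equals the number of labeled heads, which makes recall the
fraction of real heads found and lets a single merged region containing k
points count all k as detected. The running definitions are the standard
precision = TP/(TP+FP) and recall = TP/(TP+FN); dataset-level values
micro-average (pool counts, then divide). Rounding to 2 decimals happens
only at report-printing time. Counting accuracy is the squared Pearson
correlation between per-image manual totals (all labeled points,
including undetected ones) and predicted totals; because a perfect
negative relation would also give R² = 1, reports carry the regression
slope and intercept as diagnostics. Detection is evaluated independently
of counting: a region predicted 0 heads still counts as a detection if it
contains a labeled point.

Model assessment uses the six-set split: image ids are partitioned
uniformly at random into six sets whose sizes differ by at most one (52
images → four 9s and two 8s), five sets train the count model with
fivefold CV, and the designated held-out set estimates performance.

## The synthetic field generator

No real imagery ships with the package, so `generate_field_image()`
produces scenes with exact ground truth: per-pixel 7-class maps, head
centers, per-head ellipse parameters, and (through the region labeller)
per-cluster counts. It emulates the documented challenges:

* **Backgrounds**: elliptical patches of shadow (~20% area), dead leaves
  (~15%) and leaves (~20%) over a soil base.
* **Heads**: counts negative-binomial (mean 100 per 384×512 image, size
  20 — overdispersion between genotypes/plots); elliptical with major
  axis 9–16 px and aspect 0.45–0.7, in four morphs
  (white .30 / green .25 / orange .30 / brown .15); 1–3 lobes per head
  ("expanded" tiller and cluster shapes); a fraction `overlap_prob = 0.25`
  placed within one minor axis of a neighbor, producing genuine
  multi-head regions for the counter to learn.
* **Illumination**: one multiplicative gain per image, uniform on
  [0.6, 1.2] (cloudy → sunny), plus a per-channel color cast
  (SD 3%); then Gaussian pixel noise (SD 3 on the 8-bit scale).
* **Occlusion**: with probability 0.10 a head is partially covered by a
  leaf-colored blob. Blobs never cover head centers — the labeled point
  set represents a careful human annotator who marks partially hidden
  heads.

Class colors are drawn from disjoint HSV boxes (config, with tested
defaults). The boxes are designed so hue and saturation — both invariant
under a scalar gain — carry most of the class separation, and value
separates the pairs whose hue/saturation overlap (white heads vs shadow).
Brown-morph heads are rendered in a brown box but labeled as the orange
head class, since the class set has three head colors.

What the generator does **not** emulate: perspective and canopy
structure, specular highlights, motion blur, plant architecture (heads
attached to stems), within-head texture, and spatial autocorrelation of
genotypes. Consequently, passing the synthetic end-to-end thresholds
demonstrates that the pipeline's machinery is correct and that the
protocol is faithfully implemented — not that the same accuracy would be
reached on real fields, where reported precision is distinctly lower than
on these controlled scenes.

`degrade_plot_clipping()` emulates the main failure mode of per-plot
counting: plot boundaries cutting through heads. It crops the image at
the column quantiles `clip/2` and `1 − clip/2` of head-center positions,
so roughly `clip` of the heads are truncated or removed, and keeps truth
points whose centers survive. Applying it before segmentation reduces the
counting R² — the qualitative degradation expected when moving from
whole images to tightly cropped two-row plots.

## Validation design and problem sizes

The test suite checks each numerical component against an independent
oracle implemented with different algorithms: scalar textbook formulas
for HSV and Lab; brute-force flood fill for connected components;
direct moment sums, gift-wrapping hulls and BFS hole-filling for all 11
region features (random masks up to 20×20); direct matrix products for
homographies. The end-to-end experiment mirrors the study protocol at
desk scale — 52 images of ~100 heads at 384×512 px, with 17 further images for
segmentation training whose illumination gains are stratified across the
full range — emulating a training collection deliberately chosen for
lighting diversity — a scale chosen so a full run finishes in about a
minute on one CPU while keeping per-image head counts at study levels —
and asserts held-out detection recall ≥ 0.95, precision ≥ 0.85, and
counting R² ≥ 0.80. The plot-clipping comparison is made over all 52
images: R² differences over a single 8–9 image held-out set are within
sampling noise, while the full set gives the comparison adequate power.

Two empirical caveats surfaced during design and are reflected in the
tests. First, "adding head-class training pixels never removes detected
head pixels" is false for CART in general — enrichment can *correct*
false detections — so monotonicity is asserted over genuinely-head
pixels. Second, single-image-to-single-image segmentation transfer at
≥ 99% pixel accuracy requires every class pair to stay separated across
the two images' illumination; that premise holds with a fixed gain, and
the full-range illumination case is instead handled by training on
several images, as the real workflow does.

## Known limitations

* Merged clusters beyond the count cap saturate at "5+", biasing totals
  low in very dense canopies (visible as a sub-unit regression slope).
* The per-pixel classifier has no spatial regularization; precision
  depends on the minimum-area filter.
* Plot extraction consumes supplied homographies; estimating them
  (structure-from-motion, mosaicking) is out of scope.
* Heads spanning a plot boundary are credited to whichever crop window
  retains the center; real trials face the same ambiguity.
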