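---
title: "Methods: image-based screening for low-phosphorus tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based screening for low-phosphorus tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The screening problem

Phosphorus-efficient cultivars are found by growing a genotype panel under
a control and a P-deficient treatment and asking which genotypes keep
performing under deficiency. Destructive phenotyping (dry weights, tissue P)
is slow and kills the plant, so image-derived canopy geometry — projected
area, convex hull, calliper length, minimum enclosing circle (MEC),
eccentricity, leaf inclination — serves as a non-destructive surrogate
measurable at the seedling stage. This package implements the full analysis
chain: segmentation and geometry from RGB images, derived physiological
ratios, seven stress tolerance/susceptibility indices, and the multivariate
screening statistics used to pick donors. Everything is exercised on
synthetic inputs with known ground truth, because screening pipelines of
this kind are rarely published with raw images attached.

## Segmentation and calibration

A pixel is plant iff its hue, saturation and brightness each fall in a
threshold interval. The defaults — hue 60–180°, saturation ≥ 0.25,
brightness ≥ 0.20 — capture green foliage on a light background and are
fully overridable via `hsb_thresholds()`; hue intervals may wrap around
360° for non-green canopies. Segmentation optionally keeps only the
largest 8-connected component (on by default), which removes sensor
speckle and the calibration ruler; 8-connectivity is chosen so
one-pixel-wide diagonal leaf edges stay connected, matching the behaviour
of common image-analysis tools. An empty segmentation raises a typed
"no plant detected" error carrying the thresholds used, rather than
propagating an empty mask downstream.

Physical scale comes from a straight line of known length drawn over a
ruler: `calibrate()` divides the known length by the endpoint pixel
distance. The synthetic renderer records its calibration line (drawn in
pure red, outside the green segmentation window) in a JSON sidecar, which
`extract_image_traits()` reads automatically.

## Geometric conventions

All geometry uses pixel centers at integer (row, col) coordinates, 0-based,
origin top-left. Consequences worth stating explicitly:

* a single pixel has projected area of one pixel but zero hull area, so a
  filled w × h rectangle has projected area w·h px² and hull area
  (w−1)(h−1) px²;
* `projected_area ≤ hull_area` holds only after allowing one pixel of area
  per hull vertex; the tests assert the convention-exact relations instead
  of the naive inequality.

The convex hull (via `grDevices::chull`, with collinear vertices dropped)
feeds three quantities: area by the shoelace formula, perimeter by edge
sums, and the calliper (maximum Feret) length by the rotating-calipers
antipodal sweep. The minimum enclosing circle uses Welzl's
move-to-front recursion on hull vertices, deterministic (no random
shuffle) because inputs are at most a few hundred hull vertices.
Exhaustive references — maximum pairwise distance, and the smallest
covering circle over all pair (diametral) and triple (circumcircle)
candidates — ship as `bf_max_pairwise_distance()` and
`bf_min_enclosing_circle()`; the test suite demands agreement to 1e−9 px
on dozens of random masks. Containment checks use a 1e−10 px tolerance
inside Welzl (so boundary points do not recurse forever) and 1e−6 px in
the invariant tests.

"Eccentricity" is formalised as moment-ellipse eccentricity
√(1 − λ₂/λ₁) from the eigenvalues λ₁ ≥ λ₂ of the population covariance of
foreground coordinates: 0 for radially symmetric canopies, → 1 for
line-like ones. Descriptions of this trait in the phenotyping literature
("degree of radial symmetry") are loose enough to admit several
formalisations; the moment definition is adopted because it is rotation
invariant, needs no ellipse fitting step, and is the default in
scikit-image/ImageJ-style region properties.

Leaf inclination is the angle between the upward image vertical
(decreasing row direction — the stem axis in a rectified side view) and
the lamina-joint → blade vector, in [0°, 180°]. Landmarks are supplied by
the user (or by the synthetic ground truth); automatic leaf detection is
out of scope, mirroring manual ImageJ practice.

## Tolerance indices

Seven indices are computed per genotype per trait from the control mean
`y_ns`, the stress mean `y_s`, and the panel grand means (see the README
table). Two definitional choices deserve emphasis:

* **MPI** is the mean of the two treatment means, (y_ns + y_s)/2. Printed
  index tables sometimes typeset this formula ambiguously as
  "y_ns + y_s/2"; the literal reading is not unit-consistent with TOL
  (the identity y_ns = MPI + TOL/2 would fail), so the mean-productivity
  reading is used.
* **SI**, the stress intensity in SSI's denominator, follows the
  Fischer–Maurer convention SI = 1 − Ȳ_s/Ȳ_ns, computed per trait from the
  same genotype panel. Grand means are unweighted means over genotype
  means — identical to raw treatment means for balanced data, and the
  genotype-mean convention otherwise.

Missing-value policy: when SI = 0 (no panel-level stress response) SSI is
undefined and set to NA with a warning; a genotype with zero control mean
gets NA for SSI and DTE only, and genotypes lacking one treatment are
excluded from the grand means with a warning. Rankings
(`classify_genotypes()`) apply each index's selection pattern — maximum
value is tolerant for MPI/MRP/REI/STI/DTE, minimum for TOL/SSI — with
ties sharing the mean rank.

## ANOVA, heritability and variability

The two-way model Y = μ + genotype + concentration + G×C + error is fitted
to balanced replicate-level data as a fixed-effects decomposition via
`stats::aov`; the classical trial software this emulates treats
replicates/interactions as random, but for a balanced design the sums of
squares coincide and only the F denominators could differ — here all F
tests use the error mean square, and the SS% partition (each term's share
of the total SS, summing to 100) is the primary screening readout.
Unbalanced tables are rejected with instructions rather than silently
switching to Type II/III sums of squares.

Broad-sense heritability within one treatment comes from one-way ANOVA on
genotypes: σ̂²g = max(0, (MS_G − MS_E)/r), σ̂²e = MS_E, phenotypic variance
σ²p = σ²g + σ²e/r, and H² = 100·σ²g/σ²p. The truncation at zero is
standard practice and keeps H² in [0, 100]; a fully constant trait yields
σ²p = 0 and H² = NA with a warning. GCV is not printed in most trial
reports, so the standard definition 100·√σ̂²g/mean is used, reusing the
heritability components; CV is 100·sd/mean over the treatment's
observations and skewness is the adjusted Fisher–Pearson form
(`e1071::skewness`, type 2).

Pearson correlations between genotype-mean trait vectors report unadjusted
two-sided t-test p-values; screening papers star correlations without
naming a multiplicity correction, so none is applied by default, with an
optional Bonferroni flag. Multivariate stages operate on genotype means
per treatment; ANOVA and heritability use replicate-level data.

## PCA, selection and clustering

`pca_screen()` is a centred (optionally unit-scaled) singular value
decomposition; explained percentages come from squared singular values and
sum to 100. Signs are fixed deterministically — each loading vector's
largest-magnitude element is made positive — so tests and reruns agree.
`select_genotypes()` reproduces quadrant-based panel selection: genotypes
are labelled by the sign quadrant of (PC1, PC2); a genotype is superior on
a selection trait when its mean exceeds the panel mean (the mean is the
selection threshold); and a representative set covers every occupied
quadrant with, where available, both a superior and an inferior genotype.
A panel with no score or trait contrast raises a "no contrast" error.

`ward_cluster()` reproduces the heat-map analysis: optional row Z-scoring
((x − μ)/σ per row; constant rows are an error naming the row),
agglomerative clustering with Ward's D2 criterion on Euclidean distances
for both items and features, and flat labels by cutting at k clusters.
Ward-D2 merge heights are monotone, and the partition is invariant to item
order up to relabelling — both asserted in tests.

## The synthetic generators

`render_plant()` emulates the three-view camera protocol of shoot
phenotyping (top view plus front/back side views at 90°, ruler in frame)
but is deliberately schematic: leaves are filled quadrilaterals radiating
from a single stem point. Realism is not a goal; exact geometry is. Every
polygon corner sits 0.25 px off the integer pixel-center grid, so no pixel
center falls on an axis-aligned edge and rectangle areas rasterize
exactly. Ground truth is computed from the noise-free mask by independent
brute-force code (monotone-chain hull, exhaustive calliper and
enclosing-circle search) that shares nothing with the measurement
pipeline. Gaussian pixel noise, when requested, is added after the
geometry is fixed, so ground truth always refers to the noise-free mask.
`random_plant_spec()` samples rosettes of 4–8 leaves, 80–180 mm long,
6–14 mm wide, inclined 30–80° — roughly a month-old rice seedling — and
guarantees the plant fits the default 560 × 560 canvas at 1 mm/px.
One plant is rendered per image; multi-plant scenes (field protocols
photograph several plants per frame) are out of scope. Passing the
end-to-end tests therefore shows the geometry chain is exact on clean,
single-plant, known-hue images; it does not certify segmentation on field
backgrounds, overlapping canopies or mixed illumination.

`simulate_trait_table()` draws balanced genotype × treatment × replicate
tables from Y = μ + g_i + c_j + gc_ij + e with g ~ N(0, σ²g),
gc ~ N(0, σ²gc), e ~ N(0, σ²e) and c the additive deficiency shift; the
realised effects are returned so estimators can be checked against the
values actually drawn. Defaults (18 genotypes, 3 replicates) mirror a
typical hydroponic screening panel. Heritability recovery is validated at
σ²g = 4, σ²e = 1, r = 5 over 50 runs of 500 genotypes, where
E[H²] = 100·4/(4 + 1/5) ≈ 95.2%; geometry recovery uses 30 rendered views
and the geometry oracles 50 random masks — sizes chosen to make
Monte-Carlo error comfortably smaller than the asserted tolerances while
keeping a full test run under a minute.

## Known limitations

* Segmentation is plain HSB thresholding plus largest-component cleanup;
  no colour constancy, shadow handling or learning-based matting.
* Whole-plant area sums three projections and inherits the usual
  self-occlusion bias of projected-area phenotyping.
* Variance components come from balanced fixed-effects ANOVA, not REML;
  unbalanced panels must be imputed or subset first.
* The PUE denominator ("phosphorus applied") is a user-supplied positive
  scalar; its units (per plant, per litre of solution) are the
  experimenter's responsibility and the ratio is reported on that basis.
* Indices are computed per trait; no composite multi-trait tolerance score
  is attempted.
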