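---
title: "Grading carrot silhouettes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading carrot silhouettes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrotshape)
```

## The grading problem

Carrots with irregular silhouettes — forked (double or triple) roots,
pronounced curvature, broken or blunt-ended roots — are wholesome but hard
to sell, and sorting them by hand is slow. `carrotshape` implements a
machine-vision alternative: a single carrot is photographed on a bright,
contrasting background, its silhouette is segmented and described
numerically, and a Gaussian discriminant classifier assigns it to the
*regular* or *irregular* grade. This vignette explains each stage, the
assumptions behind it, the tunable parameters, and the choices made where
the design was genuinely open.

## Segmentation

The carrot is dark in the blue channel while the background is bright, so
segmentation thresholds the blue plane. The stages mirror what any
region-based pipeline would do:

1. **Threshold** (`segment_blue`): Otsu's method on the blue plane by
   default — parameter-free and well suited to the strongly bimodal
   histograms this imaging setup produces. A fixed numeric threshold and
   an `invert` flag are available for rigs with different polarity. The
   threshold used is recorded on the mask.
2. **Hole filling** (`fill_holes`): background components not connected to
   the image border (4-connected flood) become foreground. Specular
   highlights on the carrot would otherwise punch holes in the silhouette.
3. **Noise and frame removal** (`remove_noise`): 8-connected components
   touching the border while holding less than half the foreground are
   cleared (frame and margin artifacts), then only the largest component
   is kept. The `min_area_fraction` contract (default 0.05) is subsumed by
   the keep-largest rule but kept explicit in the interface.

Connectivity follows the conventional pairing — 8-connectivity for
foreground components, 4-connectivity for the background flood — which
avoids the topological paradox of both phases using the same rule. The
chain `threshold → fill → clean → fill` is idempotent, and all coordinates
are 0-based, row-major, pixel-centre.

## Whole-silhouette descriptors

With foreground area $A$ (pixel count) and perimeter $p$, the descriptors
are

$$Ro = \frac{4\pi A}{p^2}, \qquad Co = \frac{p^2}{A}, \qquad
El = \frac{a}{b},$$

where $a$ and $b$ are the bounding extents along and across the principal
(second-moment) axis. $Ro \cdot Co = 4\pi$ holds identically and is
asserted for every featurised sample. Extent is $A/(ab)$; eccentricity and
the major/minor axes come from the moment-equivalent ellipse (second
moments include the $1/12$ unit-pixel term).

**Perimeter estimation** deserves care because $Ro$ and $Co$ are
isoperimetric ratios: counting boundary pixels biases them by up to tens
of percent. The estimator used here takes the ordered boundary-pixel
chain, smooths it with a circular moving average (window 5 points) to
remove staircase quantisation, sums the polygon length, and adds $\pi$ —
the perimeter increment of offsetting a convex contour outward by half a
pixel, since boundary pixel centres sit half a pixel inside the true
outline. Calibration on analytic shapes: a digital disc of radius 60
yields $Ro = 0.995$, a square of side 100 yields $Co = 15.6$ (ideal 16),
and a rotated rectangle's perimeter is recovered within 1.5%.

A note on magnitudes: published roundness values for this task are
sometimes reported on other scales (raw values of $10^5$–$10^6$ have
appeared for comparable features); the definitions above are dimensionless
with $Ro \le 1$. Any fixed monotone rescaling of a feature leaves the
discriminant classifiers' decisions unchanged, so this is a presentation
difference only.

## Partition descriptors

The novel descriptors slice the silhouette into $n = 7$ equal-length parts
along the principal axis (`partition_silhouette`) and compare each slice
with the central slice 4:

$$Fc_i = |c_i - c_4|, \quad Fb_i = |b_i - b_4|, \quad i \in \{1,2,3,5,6,7\},$$
$$Fct = \frac{\sum_i Fc_i}{bm}, \qquad Fbt = \frac{\sum_i Fb_i}{bm},$$

with $c_i$ the slice centroid, $b_i$ the slice's maximum width and
$bm = \max_i b_i$ the biggest slice width. Design choices in these
definitions:

- **Perpendicular coordinate only.** Slice centroids differ along the axis
  by construction (about a seventh of the length each), so only the offset
  *perpendicular* to the principal axis measures shape nonhomogeneity.
  $Fc_i$ uses that coordinate.
- **Absolute values.** Signed offsets of a symmetric bend would cancel in
  the totals; magnitudes accumulate instead, and all partials are
  nonnegative.
- **Orientation-free indexing.** Parts are numbered from the thick end
  (larger terminal slice width), so a carrot laid down tip-first gets the
  same feature vector. The totals are also invariant to translation and
  180° rotation, and — being normalised by $bm$ — to scale.
- **$bm$ is the biggest slice width**, not the global bounding width; the
  two coincide for convex silhouettes, and the slice-based definition
  keeps the totals internally consistent with the partition.
- **Empty slices.** A silhouette broken into disjoint pieces can leave a
  slice with no pixels; its width is reported as 0, its centroid is taken
  from the nearest non-empty slice, and a `broken` flag is added to the
  feature row rather than raising an error.
- The raw central-slice width $b_4$ is emitted as its own column: the
  reference slice's width carries grading information (blunt broken roots
  stay wide) even though $Fb_4 \equiv 0$ by definition.

The **root count** `N` counts 8-connected components in each of the two
terminal slices and takes the larger value: a fork that has separated into
distinct tips before the terminal seventh yields 2 or 3. Using both ends
makes the feature orientation-independent.

## Discriminant classification

`shape_discriminant()` fits Gaussian discriminant analysis from scratch:
class means, priors equal to class frequencies, and either a pooled
within-class covariance (denominator $n - k$; linear boundary, LDA) or
per-class covariances (denominator $n_c - 1$; quadratic boundary, QDA).
Prediction maximises log prior plus log Gaussian density; exact ties go to
the lower class index so results are deterministic.

Two numerical safeguards, neither of which changes the unregularised
decision rule:

- **Standardisation.** Features are centred and scaled with training-data
  statistics before covariance estimation — the raw features span six
  orders of magnitude (areas of $10^4$ px² next to ratios near 1), and
  standardisation keeps the covariance solves well conditioned.
- **Ridge.** A ridge of $10^{-6}$ times the mean diagonal variance is
  added to each covariance diagonal. The root count has zero variance
  within the regular class, which would otherwise make the class
  covariance exactly singular. With `ridge = 0` a singular fit is an
  error naming the offending feature combination.

`cross_validate()` provides leave-one-out and stratified $k$-fold schemes;
standardisation and fitting happen inside each training fold only, so no
information leaks from held-out samples. Confusion matrices report
per-class recall and the overall correct classification rate
$\mathrm{CCR} = 100 \cdot \mathrm{trace}/\mathrm{total}$.

Because the evaluation protocol behind published headline CCRs for this
task is typically unstated, the pipeline reports **both** resubstitution
and cross-validated CCRs, labelled as such.

## Feature selection

`select_features()` is a sequential forward wrapper around stratified
5-fold cross-validated QDA. The first feature must strictly beat the
majority-class baseline. After that, each step adds the candidate that
maximises the CV score and accepts it as long as it does not *degrade*
the running score (by more than `delta`, default 0); selection stops when
every remaining candidate hurts. The rationale for accepting
score-neutral features: once the wrapper's CV score saturates — common on
well-separated data — a plateau carries no evidence against a feature,
and the selected set is consumed by both the quadratic wrapper and a
linear classifier, whose boundary may need features the quadratic rule
can do without. Strict-improvement stopping would freeze the set at the
saturation point and systematically starve the linear model. Fold
assignment is fixed once per run (seeded) and reused for every candidate
evaluation, so results are reproducible and ties resolve by candidate
column order.

Candidate features exclude the centroid coordinates and orientation —
they locate the carrot in the frame rather than describe its shape — and
the `broken` bookkeeping flag.

`per_feature_screen()` gives the univariate view: class means, SDs,
coefficient of variation (population SD over mean, in percent, matching
how such tables are conventionally presented) and Welch two-sample
t-tests, flagging features with $p < 0.05$.

## The synthetic generator

Real grading studies rest on photographed carrots that are rarely
deposited, so the package carries its own ground-truthed generator. A
silhouette is a tapered tube around a quadratic-arc midline:

$$w(x) = w_0\,(1 - x/L)^{\tau}, \qquad
f(x) = 4\,\kappa\,L\,\frac{x}{L}\Big(1 - \frac{x}{L}\Big),$$

with length $L$, base width $w_0$, taper exponent $\tau$ and curvature
$\kappa$ (peak midline offset as a fraction of length). Forked roots
duplicate the distal midline with symmetric angular offsets (14°) from the
branch point; broken roots are truncated with a flat cut. The rendered
width is clipped at 2 px so the digitised tip stays one 8-connected stroke
instead of fragmenting into sub-pixel specks. The RGB rendering places the
carrot (blue ≈ 50) on a bright background (blue ≈ 230) with additive
Gaussian noise, emulating the bimodal histograms of a lightbox rig.

The declared study conditions (in `inst/extdata/silhouette_ranges.yaml`,
chosen once as realistic for market carrots at roughly 3–4 px/mm and not
revisited): length 350–450 px, base width 60–90 px, taper 0.8–1.4,
orientation ±25°, noise SD 5. Regular carrots have curvature ≤ 0.02 and a
single unbroken root. Irregular carrots are curved (κ ∈ [0.08, 0.25]),
forked (2–3 roots splitting at 0.45–0.65 of length) or broken (cut at
0.35–0.65) in proportions 0.5/0.3/0.2. The standard fixture is 56 regular
and 79 irregular samples at generator seed 2020. The "upright" irregularity
sometimes listed for this task is an orientation rather than a shape, and
every descriptor here is deliberately rotation-invariant, so the generator
randomises orientation for all classes instead of treating it as a defect.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: surface texture, shadows and specular
highlights, non-uniform illumination, soil and foliage clutter,
perspective distortion, and biological width profiles more complex than a
single power-law taper. The synthetic classes are also more cleanly
separated than expert-labelled produce, which is why the pipeline reaches
CCRs at or near 100% on the fixture; on real images the same pipeline
would be expected to perform in line with published grading studies
(roughly the low-to-mid 90s), not at its synthetic ceiling.

## Numerical details and degenerate inputs

- Otsu's threshold is computed on a 256-level histogram; a constant plane
  has no threshold and is a `degenerate image` error.
- An empty foreground after cleaning is a `no object` error; a silhouette
  shorter than the part count cannot be partitioned (`too small`).
- Near-square silhouettes may swap length and width by a fraction of a
  pixel after rotation; the larger extent is always reported as length.
- The perimeter smoothing window is 5 contour points; contours shorter
  than 8 points fall back to a small-object constant.
- All tie-breaks (classifier argmax, selection candidates) resolve toward
  the lower index, declared so that tests are deterministic.
- Problem sizes used in the shipped tests: the 135-sample standard
  fixture for end-to-end checks, 500 rendered shapes for root-count
  recovery, 200 random problems for the discriminant oracle and 100
  seeded replicates for selection ordering — sizes at which the relevant
  statistics are stable while the whole suite stays quick.

## Known limitations

- Single-object scenes only; no colour calibration or illumination
  correction (out of scope for the grading task addressed).
- Part counts other than 7 are supported as a parameter but carry no
  validation beyond the 7-part scheme.
- `coef()` is defined for two-class linear fits only; quadratic rules
  have no single weight vector.
- The wrapper selection is greedy; it will not find feature pairs that
  are only jointly informative unless one of them helps marginally first.
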