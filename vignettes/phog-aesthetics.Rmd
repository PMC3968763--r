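---
title: "PHOG image statistics and perceptual contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PHOG image statistics and perceptual contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phogaes)
```

phogaes implements a complete computational-aesthetics pipeline for studies
that relate beauty judgments of images — canonically, abstract paintings —
to statistical image properties, and that measure adaptation aftereffects
("perceptual contrast") on those judgments. This vignette is the package's
own account of the models it implements, the parameters that matter, and
the design decisions taken where more than one defensible convention
exists.

## The image model: PHOG statistics

Every image is analysed at a fixed pixel budget (default 100,000 pixels,
bicubic resampling, aspect ratio preserved). Working at one fixed size
removes resolution-dependent artifacts — scanned reproductions often carry
halftone dots that only exist at high resolution — and makes gradient
statistics comparable across images of different original sizes.

The image is converted to CIE Lab (sRGB primaries, D65 white point). For
each pixel, centered differences (`[-1, 0, 1]` per axis, edge replication
at borders) give a gradient in each of the L, a, and b channels; the
channel with the largest magnitude supplies both the magnitude and the
orientation of the combined gradient field at that pixel. Taking the
channelwise maximum lets purely chromatic edges (equiluminant color
boundaries) register in the field.

A HOG feature over a region is the histogram of gradient magnitudes binned
by orientation into 16 equal bins covering 360 degrees, then L1-normalized
to sum 1. L1 normalization is what makes the histogram intersection kernel
(below) bounded by 1. A region with zero gradient mass cannot be
normalized; it is flagged *degenerate* and excluded rather than silently
zero-filled. The pyramid computes these histograms on a recursive 4-way
subdivision: 1, 4, 16, and 64 rectangles at levels 0-3. Rectangle bounds
come from integer division, with remainder pixels absorbed by the last
rectangle in each row and column.

From the pyramid:

* **Self-similarity**: for each of the 64 level-3 subimages, the histogram
  intersection `sum(pmin(h_sub, h_global))` against the level-0 histogram;
  the 64 values are aggregated by their **median** (robust to a few
  degenerate blocks; the mean is available as an option). Degenerate
  subimages contribute intersection 0; a degenerate *global* histogram (a
  constant image) makes self-similarity undefined, returned as a flagged
  `NA` rather than a number.
* **Complexity**: the mean gradient magnitude over all pixels. The
  underlying idea is the total strength of all oriented gradients; at a
  fixed pixel budget the total and the mean differ only by a constant
  factor, and the mean is explicitly size-invariant, so the package
  reports the mean.
* **Anisotropy**: the standard deviation of the normalized bin values of
  the level-3 histograms. Two pooling conventions are defensible: pool all
  16 x 64 values into one vector and take one SD (the default), or average
  per-histogram SDs (`pooling = "per_block"`). Under the pooled
  convention, identical one-hot histograms attain the maximum
  `sqrt(15)/16` (about 0.242), and uniform histograms give 0.
* **Birkhoff-like measure**: self-similarity divided by complexity, the
  order-over-complexity ratio after Birkhoff's aesthetic measure; flagged
  missing when complexity is 0 or self-similarity undefined.

Color statistics are channel means in three spaces — HSV in `[0, 1]`, RGB
in `[0, 255]`, Lab with L in `[0, 100]` — plus the fraction of pixels in
each of six 60-degree hue sectors (red centered at 0 degrees, then yellow,
green, cyan, blue, magenta). Hue is circular, but the default channel mean
is the plain arithmetic mean, matching how such tables are conventionally
reported; a circular mean is available (`hue_mean = "circular"`), and the
sector fractions are the principled way to ask hue questions. Pixels with
saturation below 0.05 are counted in an achromatic tally because hue is
numerically unstable near zero saturation.

Two conventions worth stating explicitly because the literature leaves
them open: histogram bins are filled with raw magnitude sums before
normalization (for normalized histograms, summing and per-pixel averaging
are equivalent; for complexity they are not, which is why complexity is
defined directly on the field); and the Lab conversion follows the
standard CIE sRGB/D65 pipeline — commercial tools implement slightly
different dialects, so absolute Lab values can differ by a point or two
between toolchains.

## The behavioral model

Ratings live on an integer 1-4 scale, 1 = most beautiful (school-grade
convention). A consequence used throughout: a **positive** correlation
between a feature and ratings means images with more of that feature were
judged **less** beautiful.

Raters are clustered by k-means on their rating vectors (one point per
participant in image-space, Euclidean distance). The package uses
`stats::kmeans` with 100 random restarts, seeded, keeping the best
within-cluster sum of squares; with well-separated preference groups this
protocol finds the same partition across seeds. Diagnostics over a range
of cluster counts are reported — within-cluster sum of squares, a
spherical-Gaussian BIC (shared variance `WSS/(nd)`, `kd + 1` parameters),
and Dunn's index (minimum inter-centroid distance over maximum
within-cluster diameter) — because the honest outcome on real rating data
is often that no k is clearly optimal and k is fixed by design
considerations, such as keeping at least 4 members per cluster.

Adaptor selection per cluster: rank images by the cluster's mean rating
(ties broken by image id, so the selection is deterministic and invariant
to row order); the top and bottom 15 form the most- and least-beautiful
adaptor sets, and the evaluation set is the 60 images centered on the
median of the remaining, average-rated ranking. "Average-rated" is not
further specified in this literature; the centered band is the
implementation's definition.

## Perceptual contrast

Each evaluation image is rated once after adaptation to the beautiful pole
and once after the least-beautiful pole. The per-image contrast is the
difference of pooled condition means (`after_beautiful - after_least`);
positive contrast is the headline aftereffect direction (rated less
beautiful after beautiful adaptors). The global test is a paired t-test
across unique evaluation images, pooling images over the clusters that
evaluated them by averaging within image; the correlation between the two
condition vectors is reported alongside. The sign of the published t
statistic depends on which difference the analyst takes; the package
reports t for `after_beautiful - after_least` and always reports the mean
difference, so direction is unambiguous. Degenerate tables (zero variance
of differences) are flagged, with t = 0 for identically zero differences
and signed infinity for constant nonzero ones, never a spurious p-value.

The per-cluster summary reports condition means, SDs and within-cluster
paired tests, and flags any cluster whose contrast sign opposes the
majority — the signature of an inverted aftereffect in a subgroup, which
this design can detect but not explain.

## Association layers

* **Spearman tables**: tie-corrected rho (Pearson on midranks) between
  cluster mean ratings and each property, per cluster, on the raw rating
  scale. p-values use the t approximation (`n = 150` in the reference
  design); an exact Monte-Carlo permutation p is available for small n.
  Raw p-values are reported to mirror how such tables are printed, with a
  Holm-adjusted column alongside.
* **Standardized regression**: OLS after z-scoring response and
  predictors, so coefficients are standardized betas; with one predictor
  the beta equals the Pearson correlation exactly, which the tests assert
  to 1e-12. Collinearity is surfaced via the predictor condition number
  (warning above 30), and aliased predictors are reported as NA rather
  than dropped silently.
* **Linear mixed model**: observations are (image, cluster) pairs, the
  dependent variable is the cluster mean rating, cluster is a fixed
  factor, properties are covariates, and the cluster-by-property
  interactions carry the scientific question (do preference clusters
  weight properties differently?). The only grouping factor left is the
  image, so the random structure is a random intercept per image — stated
  as an assumption. Interactions are tested with Satterthwaite F tests
  (Type III); per-cluster coefficients come from the cluster-conditional
  slopes of the fitted model. On balanced data this F agrees with the
  classical within-image ANOVA stratum, which the test suite checks
  against `aov(... + Error(image))`. Singular fits (an estimated variance
  component at zero — routine when covariates explain all between-image
  variance, as in fully synthetic data) are flagged and reported, never
  silently refitted.
* **Hue groups**: Spearman between each sector's pixel fraction and the
  cluster means, Holm-corrected across the six sectors within a cluster;
  constant sectors (grayscale collections) are flagged degenerate.
* A quadratic probe (`rating ~ z + z^2` on standardized variables) is
  provided as one concrete inverted-U test for complexity-type
  hypotheses.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without
copyrighted artworks or undeposited rating data. It has two halves.

**Images.** Constructed kinds with known gradient structure: flat fields
(degenerate by design), sinusoidal gratings, linear ramps (a single exact
gradient orientation everywhere — self-similarity 1 and pooled anisotropy
at its maximum), separable ramp mosaics (`F(x) + G(y)` with integer slopes
per strip, giving each grid cell an exactly constant, distinct orientation:
low self-similarity with near-maximal anisotropy; integer slopes matter
because 8-bit quantization of fractional slopes smears orientations across
bins), seamless periodic tilings aligned with the level-3 grid
(self-similarity 1 by construction), random-phase `1/f^slope` spectral
noise (slope monotonically controls measured complexity), and smooth
bilinear color fields. The default collection mixture spans a wide range
of every feature; the generation record (kind, slope, orientation, seed)
is returned so recovery tests can check measured orderings against
generated ones. What these images do **not** emulate: object content,
composition, scanner noise, or any property of real paintings beyond the
targeted statistics — so passing recovery tests validates the measurement
chain, not claims about art.

**Raters.** A latent-cluster linear rating model:
`rating = round(clip(a_g + w_g . z_i + eps, 1, 4))` with standardized
features `z_i`, cluster weight vectors `w_g`, intercepts `a_g`, and
Gaussian noise (sd 0.5 by default). This linear-Gaussian form is the
package's modelling assumption, not an empirical claim. Defaults mirror
the reference design: 50 raters in 7 clusters of sizes 10/9/7/7/7/6/4
(minimum 4), qualitatively distinct weight vectors (some clusters penalize
self-similarity, others reward it; most reward brightness or saturation to
different degrees), and intercepts whose participant-weighted mean (~2.91)
was calibrated once so that the clipped-and-rounded grand mean lands near
2.88, the anchor scale of the reference study — with cluster 5 the
deliberately more generous group. Adaptation shifts the latent rating
symmetrically by half the condition shift in each direction
(`delta_i = delta0 + delta1 * z_ss`, default `delta0 = 0.16`,
`delta1 = 0`), so the condition-free expectation equals the baseline
model; the mechanism behind such shifts (adaptation proper vs criterion
shift) is deliberately left open, and the generator is agnostic about it.
A per-cluster sign flip is available to emulate a subgroup with an
inverted aftereffect, and condition order is counterbalanced and recorded
but, matching the analysis layer, never modelled. An image-level shortcut
(`simulate_contrast_means()`, per-image SDs 0.16/0.085 giving
per-condition SDs near 0.19 and a paired correlation near 0.8) supports
calibration and power studies of the paired test at 132 images without
the participant layer.

## Numerical choices and degenerate inputs

* Zero-magnitude pixels carry sentinel orientation 0 and contribute no
  histogram mass.
* Bin edges are half-open, `[(b-1) * 22.5, b * 22.5)` degrees.
* The anisotropy SD is the sample SD; over 1024 pooled values it differs
  from the population form by under 0.05%.
* Resampled pixel values are clamped to `[0, 255]` and rounded, keeping
  every image a valid 8-bit grid.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  images, populations, and whole pipeline runs are bit-reproducible; the
  test suite asserts byte-identical CSV output across reruns.
* Ties in adaptor ranking break by image id; k-means label permutations
  are handled by comparing partitions (ARI), never raw labels.

## Problem sizes

The package's reference configuration — 150 images at a 100,000-pixel
budget, 50 raters, 7 clusters, 15/15/60 adaptor and evaluation sets —
runs the full pipeline in under a minute on one core. Unit tests use
smaller collections (24-60 images, reduced pixel budgets) and the
brute-force oracles run on images up to 32 x 32, sizes at which a
double-loop reimplementation is still exact and fast. Calibration checks
of the paired test use 1000 null replicates at 132 images via the
image-level shortcut.

## Known limitations

* The rating model is linear in standardized features with additive
  Gaussian noise; real raters are neither linear nor homoscedastic, and
  the 1-4 scale is coarse. Recovery results quantify the pipeline, not
  human behavior.
* Arithmetic hue means inherit the circularity artifact on purpose (for
  comparability with published tables); use the circular mean or the
  sector analysis for substantive hue questions.
* The Lab conversion dialect (sRGB/D65 CIE pipeline) can differ from
  commercial tools by small absolute offsets.
* The mixed model fixes the random structure to an image intercept; richer
  structures (e.g., random slopes) are out of scope.
* With synthetic raters derived from the features themselves, regressions
  of ratings on features are far more predictable than published values
  from human data — a property of the generator, not a reproduction claim.
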