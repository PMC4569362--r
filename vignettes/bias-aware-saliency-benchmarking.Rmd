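---
title: "Bias-aware benchmarking of saliency maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware benchmarking of saliency maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saliencybench)
```

## Scope and model

`saliencybench` evaluates topographic saliency maps against two kinds
of human ground truth: eye-tracking fixations gathered under three
task conditions (free viewing, object search, saliency viewing) and
explicit judgments — locations observers manually select as most
salient. All point data share one representation (image, observer,
task, x, y, ordinal), with 0-based pixel coordinates, `x` the column
and `y` the row, and grids stored `(row, col)`. One stated convention
throughout the package prevents the transposition errors endemic to
gaze data; importers for external datasets must document their own
mapping onto it.

## ROC scoring and tie handling

Both AUC variants are computed as the normalized Mann–Whitney U
statistic with midranks:

$$\mathrm{AUC} = \frac{1}{n_+ n_-}\Big(\sum_{i \in +} r_i - \tfrac{n_+(n_++1)}{2}\Big),$$

where ranks are taken over the pooled map values at positive and
negative locations. This equals trapezoidal integration of the ROC
curve over all thresholds, handles tied map values exactly (a
constant map scores exactly 0.5), and is checkable against an
exhaustive pairwise-comparison oracle, which the test suite does to
1e-12 on instances with up to 10^4 pairs. AUC is invariant under any
strictly increasing transform of map values, so no map normalization
is required before scoring.

**Standard AUC** draws `ceiling(n_neg_ratio * n_pos)` negatives
uniformly from the image's non-positive pixels (default ratio 1,
balanced). The literature varies in how this negative set is built, so
the ratio and the seed are explicit arguments. **Shuffled AUC** takes
its negatives from points selected on *other* images — the negative
sample then carries the same spatial distribution as the positives,
and any map component that depends only on position scores at chance.
Pool size is capped at `max_neg_ratio` (default 10) times the
positive count by seeded subsampling to bound cost. Pool entries
falling on positive pixels are excluded; note this exclusion is only
negligible when the grid is large relative to the sample (the chance
check of this property uses a 512×512 grid with 2000 points per side —
on small grids the exclusion hollows out the pool's center and
inflates the score, a finite-size artifact rather than a property of
the statistic).

## Blur levels and density maps

Discrete points become continuous density maps by binning into a
per-pixel count map, convolving with an isotropic Gaussian, and
renormalizing to unit mass. Blur is parameterized as a dimensionless
integer level: `sigma = blur_level * sigma_per_level * max(height,
width)` pixels, with `sigma_per_level = 0.01` so one level is 1% of
the larger image dimension. The level-to-sigma mapping is a package
convention (the literature reports levels without defining them), kept
explicit and configurable everywhere it enters.

Convolution is a hand-written separable kernel truncated at 4
standard deviations, zero-padded. The alternative — FFT convolution
with circular boundaries, as image packages default to — wraps
probability mass across opposite image edges, which is wrong for gaze
data. Two boundary policies are used deliberately: density maps
renormalize total mass after zero-padded smoothing (mass near edges
stays near edges), while predicted judgment maps use edge-corrected
convolution (dividing by the blurred all-ones mask). Without the
correction, smoothing alone dims every map's borders, injecting an
artificial central emphasis into any blurred prediction — enough to
push a label-permuted control predictor visibly above chance.

## Inter-observer congruency

IOC answers "how well do the remaining observers predict a held-out
observer?": for each observer of an (image, task) pair, the others'
points are blurred into a density map and the held-out points are
scored against it with standard AUC; the per-image IOC is the mean
over observers and the dataset IOC the mean over images with at least
two observers. The inner metric and its blur (default level 3) are
arguments; standard AUC is used because IOC is conventionally read as
the ceiling for standard-AUC benchmarking. Whether dataset-level IOC
should pool fixations instead of averaging per-image scores is
genuinely open; averaging was chosen because it weights images
equally, matching how algorithm scores are aggregated.

## Spatial bias and its removal

An algorithm's spatial bias over a dataset of N maps is estimated by
whitening each map to zero mean and unit standard deviation,
averaging the whitened maps, and subtracting the grand mean: content
uncorrelated across images averages out, leaving the positional
preference. Population (divide-by-n) standard deviations are used
throughout — this makes the N = 2 whitening case exactly (−1, +1) and
reads "standard deviation of a map" as a descriptive statistic.
Constant maps (or, in pixel-wise whitening, locations constant across
maps) are errors naming the offender, never silently zeroed:
pathological input should surface, not vanish.

Removal offers two normalizations of a map ensemble:

- **Rank ordering**: at each pixel, the N values across maps become
  ascending ranks divided by N, imposing the same uniform value
  distribution at every location; per-pixel sums equal `(N+1)/2` for
  tie-free input. Ties take midranks — the reference procedure is
  silent on ties, and midranks avoid order dependence while keeping
  the sum property in expectation. Rank output is invariant under any
  strictly increasing transform applied to the ensemble.
- **Whitening**: maps are whitened individually, then each pixel
  location is whitened across maps; per-pixel sums are 0 and
  variances 1. The pixel-wise stage is idempotent; the two-stage
  composition is not (re-whitening each map perturbs the pixel-wise
  result), so the idempotence property is stated — and tested — for
  the pixel-wise stage.

After either normalization, standard and shuffled AUC agree closely
(within 0.02 per algorithm on the default synthetic study), since the
spatial component both metrics disagree about has been removed.

## The judgment predictor

The predictor is an ensemble of bagged regression trees (a random
forest regressor; `randomForest` with bootstrap per tree and
`ceiling(sqrt(d))` features per split) over per-pixel features:
one column per saliency algorithm, optionally the blurred free-viewing
fixation density, optionally `x/width` and `y/height`. Training images
contribute every explicit-judgment point as a positive and
`n_neg_per_image` seeded uniform non-positive pixels as negatives
(default 100, matching the judgment count per image, so classes are
balanced; the exclusion radius around positives is 0 — only exact
positive pixels are excluded — configurable). Images are split
half/half into train and test by seeded shuffle, and evaluation
refuses any train/test overlap outright rather than trusting callers.
Defaults of 15 trees and post-processing blur level 4 are the
package's standard operating points; tree-count and blur sensitivity
are part of the evaluation protocol rather than hidden constants.
Center-bias removal is deliberately not applied here: spatial position
is typically itself a feature, so removing it from the inputs while
feeding coordinates would be incoherent.

## Simulating explicit judgments

A predicted judgment map is min-max normalized; locations below a
threshold (default 0.1 of the normalized range) are excluded; the
remaining pixels are sampled with replacement, probability
proportional to value, for `n_points` draws (default 100, the typical
human judgment count per image). Sampling *with* replacement is
intentional: human judgment points can coincide and multiplicity is
informative. Draw frequencies are validated against the
thresholded-renormalized map by chi-square goodness of fit. Surrogate
benchmarking then scores every algorithm against both true and
simulated points and correlates the two score vectors (Pearson by
default, Spearman optionally); both vectors draw their ROC negatives
from one shared seeded substream, so identical point sources receive
identical scores and the self-comparison correlation is exactly 1.

## The synthetic study

The generator emulates the structure — not the appearance — of a
multi-task gaze-plus-judgment dataset. Each 64×64 scene holds 1–few
Gaussian blobs (centers ≥ 15% of the image dimension from borders,
sigma 5–12% of it, weight 0.5–1.5); the normalized mixture is the
scene's latent salience. Observers draw each point from
`(1 − w)·latent + w·central Gaussian` with task-specific center
weights 0.5 (free viewing), 0.3 (saliency viewing), 0.2 (object
search), 0.05 (explicit judgment) — encoding the qualitative ordering
that free viewing is most center-biased and explicit judgment least —
plus 1 px jitter. Defaults are 20 images, 10 observers × 10 points
per task (so 100 judgment points per image), and six synthetic
algorithms whose maps are `latent + noise + central bump`, crossing
fidelity (noise sd 0.08–0.6) with built-in center bias (bump amplitude
0–2). Crossing the two axes is what makes the fairness analyses
non-trivial: the roster contains a high-fidelity unbiased algorithm
and a low-fidelity strongly biased one that raw standard AUC ranks in
the wrong order and de-biased AUC ranks correctly.

Everything is a pure function of (config, seed): scenario generation,
training, prediction, simulation, and benchmarking rerun from their
manifests byte-identically, which the suite asserts at the file level.

What passing these tests shows — and does not. The generator captures
center bias, task differences, observer variability, algorithm
fidelity and algorithm bias, so it exercises the *evaluation
machinery* end to end. It does not capture real image statistics,
saccade dynamics, temporal order, per-observer idiosyncrasies, or the
failure modes of real saliency algorithms; numbers obtained on it
characterize the methods, not any real dataset or published model.

## Problem sizes and numerical choices

Test and acceptance runs use 64×64 grids (small enough that
exhaustive pairwise AUC oracles and byte-level rerun comparisons stay
cheap), 512×512 only for the finite-size-sensitive shuffled-AUC
chance check, 2000-point samples for distributional checks and 10^5
draws for the sampler's goodness of fit. Degenerate inputs error
early and name the offending row, map, or pixel: out-of-bounds
points, constant maps in whitening, empty masks, empty thresholded
maps, single-observer IOC, single-class training labels, train/test
overlap. Map files are grayscale PNG, read at 8- or 16-bit depth and
scaled to [0, 1]; 16-bit output uses a minimal in-package encoder
(the CRAN `png` writer is 8-bit only) and is round-trip-verified
against `png::readPNG`. De-biased maps, whose values leave [0, 1],
are exported min-max rescaled with a JSON sidecar recording each
map's original range so values are recoverable.

## Known limitations

- The blur-level-to-sigma mapping is a convention; comparisons with
  other implementations must match conventions first.
- Shuffled AUC on small grids with dense positives is distorted by
  the positive-exclusion rule (see above); prefer larger grids or
  sparser samples.
- The bias model is centered and isotropic; off-center or anisotropic
  spatial biases are quantified by `spatial_bias_map()` but the
  synthetic generator does not produce them.
- Parametric models of center bias, per-observer bias models, and
  other saliency metrics (NSS, CC, KL, EMD) are out of scope.
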