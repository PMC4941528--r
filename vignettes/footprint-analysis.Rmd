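---
title: "Footprint morphometrics, body-mass estimation and trackway comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint morphometrics, body-mass estimation and trackway comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

# Overview

`footprintr` implements a quantitative workflow for comparing fossil hominin
footprints with experimentally produced modern human footprints:

1. **Geometry** — orient a 3-D footprint surface so that a best-fit plane
   through the undisturbed sediment surrounding the print becomes the X-Y
   plane, then measure impression depths at 14 functionally relevant
   anatomical landmarks (medial/lateral heel, medial/lateral midfoot, five
   metatarsal heads, five toes).
2. **Body mass** — predict the track-maker's mass from five external print
   dimensions with a bagged regression-tree ensemble, benchmarked against a
   length-only linear regression, aggregating trackways by their average
   print dimensions.
3. **Gait** — classify prints as walking or running so that fossil trackways
   are compared only against human prints of the matching gait.
4. **Morphology** — test whether a trackway's mean 14-region depth topography
   lies within the range of human variation, using a subject-level
   resampling Mahalanobis null distribution.
5. **Sex attribution** — attribute sex to trackways by the mean method and
   summarise group composition per site.

Because the underlying experimental measurement data are not redistributable,
the package ships a synthetic footprint generator with known ground truth.
All statistical guarantees quoted below are properties demonstrated *on that
generator* by the test suite and `scripts/acceptance.R`; none are measurements
of real footprints.

# Surface orientation and depth measurement

A `footprint_surface` is a gridded elevation field (cm) with an
undisturbed-margin mask, an optional print-outline mask and 14 landmark
coordinates. `fit_reference_plane()` fits `z = ax + by + c` by least squares
over the margin cells and reports the residual RMS; `orient_surface()`
replaces elevations by residuals from that plane, making orientation
idempotent. `measure_depths()` samples the oriented field at the landmarks by
bilinear interpolation, positive downward. Design choices:

* **Landmark identification is an input.** Landmarks are taken from
  annotations, not detected automatically; automatic outline segmentation is
  out of scope.
* **Point sample vs. local minimum.** Depths default to interpolated point
  samples at the landmark; `method = "local_min"` instead takes the deepest
  grid node within a configurable radius (default 0.5 cm), for workflows that
  treat a landmark as a small neighbourhood.
* **Sign convention.** Depths are positive downward everywhere in the
  package. Negative values (a raised displacement rim under a landmark) are
  legal but flagged with a warning.
* **Mean depth has two estimators** because "average depth" of a print is
  ambiguous: the mean over print-outline cells (default for surfaces) and the
  mean of the 14 regional depths (used for tabulated profiles). On generated
  surfaces the two differ by a multiplicative offset that is near-constant
  for a fixed pit geometry; the form used is recorded in the result's
  `source` attribute. The mass model does not care which is used as long as
  training and prediction use the same form — synthetic tables use the
  generated mean depth.

The **forefoot depth gradient** summarises medial weight transfer: the
least-squares slope of depth against medial-to-lateral position 1..5 across
the metatarsal heads and across the toes. Habitually barefoot human walking
prints show negative slopes (medial deeper), reflecting toe-off through the
first two digits; a flat or positive slope is the diagnostic signature of a
divergent, non-human gait pattern.

# Body-mass estimation

`fit_mass_model()` grows `n_trees = 500` regression trees, each on an
n-with-replacement bootstrap of the training prints, with conventional
regression-forest defaults: `mtry = ceiling(p/3) = 2` of the `p = 5`
predictors tried per split and minimum node size 5, trees otherwise grown to
full depth. These hyperparameters are the standard defaults of the method;
nothing here is tuned. The five predictors are heel-to-hallux length,
heel-to-second-toe length, forefoot breadth, heel breadth and mean depth.
Predictions are means over trees and hence always fall inside the training
response range — the estimator cannot extrapolate beyond the masses it has
seen, which is the desired behaviour for fossil inputs.

Bootstrap bookkeeping is kept per tree: for `n` training prints the expected
number of unique in-bag points is `n(1 - (1 - 1/n)^n)`; at `n = 343` this is
about 217 in-bag and 126 out-of-bag, and the out-of-bag predictions give an
internal RMSE without touching the test set. The 217/126 split is an
expectation of the bootstrap, not a fixed quota.

Two split modes are exposed because repeated prints per subject create a
leakage risk: `by = "subject"` (default) keeps each subject's prints on one
side of the 70/30 partition; `by = "print"` partitions rows directly and
yields the familiar 343/147 sizes at n = 490. The default is the
conservative choice; both are seeded and recorded.

`fit_length_regression()` is the deliberately simple benchmark: ordinary
least squares of mass on heel-to-hallux length. `evaluate_mass_models()`
scores both on identical test rows. Fossil trackways are predicted from the
average print dimensions of the trackway (`predict_trackway_mass()`), not by
averaging per-print predictions; missing predictors in a fossil print simply
drop that print from the average, and a trackway with no complete print is
an error rather than an imputation (imputation would silently move fossil
predictions toward the training median).

# Gait classification

The gait module uses the same bagged-tree machinery (classification trees on
the five dimensions plus the 14 depths) for coherence with the mass model;
the choice of classifier family is an interpretation, since only the
existence of a trained classifier is specified by the workflow this package
reproduces. A trackway's label is the majority vote over its prints' labels,
reported with the winning vote fraction; ties break toward walking — walking
dominates both the reference activity and the fossil interpretation — and
are logged. The out-of-bag error rate is attached to every fit, and a
permutation check (labels shuffled, error near 50%) is part of the test
suite.

# The resampling Mahalanobis comparison

For a fossil trackway with `k` prints the null distribution answers: *how far
does the average of k prints from one human subject typically fall from the
average human footprint, in covariance-scaled units?* Per iteration:

1. draw one subject uniformly among eligible subjects (uniform over
   *subjects*, not prints, so prolific subjects are not over-weighted);
2. sample `k` of that subject's prints — without replacement by default, a
   subject with fewer than `k` prints being ineligible; a with-replacement
   mode is exposed;
3. average their topographies region-by-region;
4. recompute the mean and covariance from all prints of the *remaining*
   subjects (the "rest of the humans"); a fast mode reuses the full-pool
   covariance, whose small bias is documented here: it slightly shrinks
   distances because the sampled subject's own prints inflate the pooled
   covariance;
5. record the Mahalanobis distance `sqrt(d' S^{-1} d)`.

The fossil distance is computed between the trackway's mean topography and
the pool's overall mean under the pooled covariance, and the reported
probability is the exceedance fraction with a +1 correction,
`p = (1 + #{null >= d}) / (1 + N)`, so a finite null can never produce an
exact zero. Numerical notes:

* Distances are computed from the Cholesky factor; a singular covariance
  raises an error that names the regions dominating the deficient
  directions. With 14 dimensions a small gait-matched pool can be
  ill-conditioned, so a Ledoit-Wolf shrinkage estimator (identity target,
  analytic intensity) is available via `estimator = "shrinkage"`.
* The degenerate pool in which every sampled mean coincides exactly with the
  out-of-sample mean is defined to have distance 0 regardless of the
  covariance.
* The pool mean defaults to the per-print grand mean; a
  per-subject-then-average mode is exposed because the workflow's phrasing
  does not resolve which was intended.

Calibration is a property, not an assumption: with an exchangeable pool
(i.i.d. multivariate-normal profiles, 41 subjects by 12 prints) and held-out
human subjects treated as fossils, the test suite requires the empirical
type-I error at alpha = 0.05 to lie in [0.02, 0.10] over 500 replicates of
2,000 iterations, and approximate uniformity of the p-values. Power is
exercised against a template whose forefoot mean is moved 3 pooled SDs along
the unit-norm lateral-deepening direction: such trackways must be rejected
at alpha = 0.05 in at least 95% of runs. A 3-SD shift is detected by the
14-dimensional distance long before the forefoot slope itself changes sign;
sign reversal of the template gradient requires a considerably larger shift,
which the geometry tests exercise separately.

# Sex attribution by the mean method

The threshold is the mean of the non-excluded predicted trackway masses,
computed assemblage-wide by default (a per-site option exists). Strictly
above the mean is predicted male, below female; a mass exactly at the mean is
assigned female with a logged tie note — the conservative direction, since
the method is already expected to under-count males when dimorphism exceeds
that of the calibrating population. Exclusions are manual flags (e.g. an
extreme low outlier representing a child) or an optional modified z-score
rule (0.6745 (x - median)/MAD < -3.5, off by default). Composition reports
conserve counts: males + females + excluded equals trackways, per site and
overall. Individual-identity linking across trackways (whether 23 trackways
represent 15 or 23 individuals) is out of scope and the reports treat each
trackway as one prediction.

# The synthetic generator

The generator emulates the structure of the experimental reference data the
analysis was designed for: 41 subjects (15 adult males, 14 adult females, 10
juvenile males, 2 juvenile females) each producing about a dozen prints under
varied substrate conditions, with sex-dimorphic adult masses. Defaults, with
the reasoning behind each:

* **Masses**: adult male/female means 56/49 kg with SD 5.5 kg, juveniles
  28-32 kg (mean 30, SD 7), all truncated at > 15 kg to avoid non-physical
  draws. These produce an overall mean and spread comparable to the
  reference population (mean near 49 kg, SD near 10 kg, range from the upper
  teens to the high 60s).
* **Dimensions**: heel-to-hallux length follows an allometric power law
  `L = 6.8 * mass^(1/3)` (isometry; about 25 cm at 50 kg). A subject-level
  size factor (CV 0.05) makes length an imperfect mass predictor, putting
  the length-only regression error in the several-kg range reported for such
  regressions; print-level noise CV is 0.02. Relative breadths respond to
  the subject's mass-for-length residual with exponent 0.5 — heavier-than-
  their-foot-length subjects leave relatively broader prints — which is what
  makes the multi-dimension ensemble genuinely more informative than length
  alone. Both pathways are biological commonplaces; the specific constants
  are the generator's own calibration, fixed once.
* **Depths**: mean print depth is `2.0 cm * (mass/50)` scaled by a substrate
  multiplier (0.6 dry/compacted, 1.0 moist/firm, 1.5 wet/soft, drawn per
  print) with 10% noise. The 14-region profile is the gait template's
  multivariate normal draw scaled by the print's mean depth.
* **Templates**: the walking template encodes strictly decreasing depth
  mt1 > ... > mt5 and toe1 > ... > toe5 plus a shallow medial midfoot (the
  arch); the running template deepens the forefoot uniformly and flattens
  the gradient. Shape noise is 12% per region with compound-symmetric
  correlation 0.3 (guaranteed positive definite). Divergent "Laetoli-like"
  templates shift the forefoot mean along the unit-norm lateral-deepening
  direction by a configurable number of pooled SDs; zero shift is the
  identity.
* **Surfaces**: a tilted plane plus 14 negative Gaussian pits at
  anatomically arranged landmark positions snapped to grid nodes (spacing
  0.25 cm), so noiseless surfaces reproduce their generating profile to
  1e-6 cm after plane fit and orientation. The default pit radius (SD
  0.25 cm) keeps neighbouring landmarks' pits numerically independent;
  repeatability experiments use wider, well-separated pits because that is
  the regime where replicate landmark placement error (SD 0.05 cm) produces
  sub-0.01 cm depth differences.

What the generator does **not** emulate — and therefore what passing tests do
not show about real data: photogrammetric reconstruction error, erosion and
taphonomic overprinting, substrate mechanics beyond a per-print scalar
multiplier, the preservation bias by which only a range of body masses
leaves discernible tracks, distinct juvenile foot shape (juveniles are
scaled-down adults, since the workflow treats the one child track only by
size), and any real covariance structure between dimensions and depth shape.
Calibration experiments use an idealised exchangeable pool (i.i.d.
multivariate-normal profiles) because the calibration claim itself assumes
exchangeability; the full generator's subject-level depth scaling
deliberately violates it, as real repeated prints do.

# Problem sizes and reproducibility

The test suite and acceptance script run at the sizes the analyses are
designed around: populations of 41 subjects and roughly 490 prints; 500-tree
ensembles; 70/30 splits; resampling nulls of 2,000 iterations inside
replicate studies (500 replicates for calibration, 100 for power) and 10,000
iterations for single-trackway comparisons; 1,000 simulated assemblages of
16 trackways for the mean method. All randomness flows from named integer
seeds recorded in outputs; the pipeline writes a JSON manifest (seeds,
configuration, input digests) and regenerates byte-identical report tables
from identical seeds.

# Known limitations

* The gait classifier reproduces a *role* (gait matching), not a documented
  algorithm; its feature set and family are this package's choices.
* The resampling test's leave-subject-out covariance differs by one subject
  between the fossil comparison (full pool) and the null iterations; the
  discrepancy vanishes as subjects grow and is covered by the calibration
  band.
* Surface input is limited to gridded heightmaps (ASCII XYZ plus a landmark
  sidecar); triangulated meshes must be rasterised upstream.
* The mean method is a coarse classifier: accuracy targets of ~70-80% under
  1.5 SD dimorphism are properties of the method, not of this
  implementation, and it systematically under-counts males in male-biased,
  highly dimorphic groups — the direction of that bias is itself tested.
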