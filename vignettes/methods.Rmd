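---
title: "Decomposing symmetric and asymmetric shape variation in repeated outline modules"
author: "morphosym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing symmetric and asymmetric shape variation in repeated outline modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosym)
```

## The problem

Many organisms build their bodies from repeated, bilaterally symmetric
modules. The motivating case is a siphonous green macroalga whose
thallus consists of flattened calcified segments strung along each
branch: every segment of a plant is genetically identical to its
neighbors, is mirror-symmetric about the axis running from its basal
node to its apex, and is digitized as a closed outline of
semilandmarks. Shape differences among such modules then decompose into
biologically distinct channels:

* **symmetric variation** among segments, plants and localities
  (plasticity, and its allometric part — covariation with segment
  size);
* **directional asymmetry (DA)**: the mean left–right difference shared
  by the segments of one plant, e.g. from one-sided shading;
* **fluctuating asymmetry (FA)**: each segment's own random deviation
  from its plant's mean asymmetry, the classic proxy for developmental
  instability;
* **measurement error**: the difference between two independent
  digitizations of the same outline.

A crucial structural feature is *side ambiguity*: the modules have no
front/back differentiation, so "left" and "right" cannot be matched
across plants. DA and FA are therefore only ever defined *within* a
plant, and the nested models below never compare sides across plants.

## Data model and superimposition

An outline is `k` ordered 2D points: one fixed landmark at the basal
node and `k - 1` semilandmarks around the curve (the study scheme uses
`k = 90` with points 1 and 46 on the symmetry axis and point `i` paired
with `92 - i`). A `LandmarkScheme` carries this contract; an
`OutlineSet` holds configurations plus the locality/plant/segment/
replicate metadata.

Superimposition is generalized Procrustes analysis (GPA) in the
*partial Procrustes* convention: every configuration is centered,
scaled to unit centroid size, and rotated (proper rotations only) to
the iteratively refined consensus; convergence is declared when the
consensus moves less than `1e-7` between iterations (far below any
reported precision; 100 iterations maximum). The consensus is oriented
so its symmetry axis is vertical with the fixed landmark at the bottom,
which makes PC signs and DA directions reproducible run to run.
Analyses use coordinates projected orthogonally to the tangent space at
the consensus; distances are tangent-space ("Procrustes") distances.

Semilandmarks can be treated three ways, run as parallel *treatments*:

* `unslid`: equidistant points treated as fixed landmarks;
* `min_be`: points slide along tangent chords to minimize the
  thin-plate-spline bending energy relative to the current consensus.
  The TPS kernel is `U(r) = r^2 log r`; since bending energies are only
  ever compared, the constant factor separating this from the
  `r^2 log r^2` convention is immaterial but fixed. The slide is the
  exact minimizer of the quadratic form along all tangents jointly, and
  the bending matrix annihilates affine fields, so the energy of any
  affine deformation is zero.
* `min_pd`: each point independently slides to the foot of the
  perpendicular from its consensus partner onto its tangent line. On
  variable material this criterion is known to let points overtake
  their neighbors; the package counts these events
  (`diagnostics$slideBehindPerCycle`) and reports them rather than
  silently fixing them, and the pipeline excludes `min_pd` from
  downstream symmetry analysis by default for exactly this reason.

Sliding runs for 3 slide/re-superimposition cycles by default, with the
consensus (and bending-energy kernel) refreshed each cycle; a fixed
consensus is a matter of passing `nIter = 1` repeatedly, and
convergence is additionally visible in the per-cycle diagnostics.
`treatmentEffectAnova()` quantifies what a treatment does to each
segment's shape against the digitization error, using a sequential
decomposition (segment, then treatment-within-segment) on the jointly
superimposed data.

## Object symmetry

Each configuration enters the symmetry analysis twice: as itself and as
its reflection across the vertical axis with left/right point labels
swapped (`reflectRelabel`; the two on-axis points keep their labels).
A single GPA of all originals and copies followed by a covariance PCA
yields axes that are *exactly* symmetric or asymmetric, because the
empirical covariance between the symmetric and antisymmetric subspaces
cancels pairwise. Axes are classified by the correlation between
original and reflected scores (threshold 0.99; anything between the
thresholds would indicate numerically tied eigenvalues and raises a
warning). The per-object symmetric component is the mean of the two
aligned copies, the asymmetric component half their difference.

**Total shape asymmetry** is, by default, the Euclidean norm of an
object's PC scores over the asymmetric axes. The phrase "adding the
Euclidean distances of the PC scores" admits a second reading — the sum
of absolute per-axis scores — and both statistics are computed
(`totalAsymmetry(dec, "abssum")`). The Euclidean norm is the default
because it equals the tangent-space norm of the asymmetric component
(making it independent of the eigenbasis) and is invariant to the
original/reflected choice; discriminating between the two definitions
empirically would require a reference coordinate dataset, so the
choice is documented rather than fitted.

## Allometry

`fitAllometry()` regresses all shape coordinates jointly on centroid
size (raw size by default, the convention for static allometry of
modules at one developmental stage; `logSize = TRUE` is available).
Reported are the percentage of shape variance explained and Wilks'
lambda, computed on the principal-component basis of the shape data
because raw Procrustes coordinates are rank-deficient and the
determinant is otherwise undefined; with one centered predictor the
statistic reduces to `1 - sum(q_j^2 / t_j)`, which also makes the
999-permutation test (p-value convention `(b + 1)/(n + 1)`) cheap.
`sizeAdjust()` removes exactly the fitted allometric subspace, with
exact sequential SS additivity. The regression uses the combined
original-plus-reflected dataset, the same data the symmetry PCA and
the nested model see (sizes are identical for the two copies of an
outline); an originals-only fit is a matter of subsetting.

## Nested Procrustes ANOVA

The multivariate model decomposes the combined dataset (each segment in
four instances: 2 digitizations x original/reflected) with sequential
(type I) sums of squares in the fixed order

> [centroid size,] locality, plant (locality), segment (plant),
> side (plant), segment x side (plant), measurement error,

where multivariate SS are traces of effect cross-product matrices —
identical to summing univariate SS over coordinates and to the
squared-tangent-distance formulation. F ratios follow the nesting:
locality over plant, plant over segment, segment and side (DA) over
their interaction (FA), and FA over measurement error. Degenerate
denominators yield a flagged `NA` rather than infinity.

The sequential decomposition is computed exactly but without large
model matrices: the model space of [size, nested factor] splits
orthogonally into the factor's indicator space plus the component of
size orthogonal to the factor's group means, so each increment is a
closed-form projection of group sums. Because centroid size is the same
for the original and reflected copy of a digitization, the covariate is
orthogonal to the side and interaction subspaces, and those two rows
are bit-for-bit unchanged by size adjustment — asserted in the tests at
1e-8. Size *does* differ slightly between replicate digitizations, so a
small part of the measurement-error SS is absorbed by the covariate;
the residual degrees of freedom drop by one accordingly.

P-values come from restricted permutations that only shuffle the
exchangeable units of each effect: whole plants across localities;
whole segments across plants within locality; symmetry copies across
segment-side cells within plants (serving both the segment and the side
test); and individual records across the four cells of their segment
(FA against error). Observed statistics are recomputed with the same
formulas under each permutation, `p = (b + 1)/(n_perm + 1)`, 999
permutations by default — so the smallest attainable p-value is 0.001.
The calibration of all five schemes is verified empirically: under a
fully null generator the p-values are uniform (Kolmogorov–Smirnov,
220 simulations in the acceptance suite).

The univariate analogue (`totalAsymmetryAnova`) decomposes total shape
asymmetry (two records per segment) into locality, plant, segment and
measurement error, with F ratios locality/plant, plant/segment,
segment/error and the corresponding restricted permutations.

`perPlantDecomposition()` repeats the segment/side/interaction/error
decomposition inside each plant, reporting MS and R-squared per
component without p-values — with around ten segments per plant these
are comparison statistics, not tests. Localities are compared by
bootstrap percentile intervals of the difference in medians
(two-sided p floored at `1/n_boot`), and `msCorrelations()` reports the
Pearson correlations of the per-plant MS components.

## The synthetic generator

`generateOutlines()` produces a fully controlled stand-in for field
data, so every stage is testable without any download. A segment is
built from an exactly mirror-symmetric bean-shaped base outline
(cosine-only radial series, arc-length-equidistant points, point 1 at
the basal pole) plus deformation fields constructed in explicitly
symmetric or antisymmetric Fourier bases of the point index — injected
DA/FA therefore lives exactly in the asymmetric subspace and variance
bookkeeping is exact. All fields are orthogonalized against the
similarity directions (translation, scaling, rotation) at the base
shape, so injected variance survives superimposition instead of being
absorbed by it. Field variance decays geometrically across modes, with
the leading symmetric direction shared with the allometric deformation;
this anisotropy reproduces the dominance of a single "conic-to-bean"
trend (PC1) seen in real segment data.

The hierarchy: localities set median centroid size; plants draw a size
factor, a symmetric shape field and a DA field; segments draw a size, a
symmetric field and an FA field; each segment is digitized twice with
independent coordinate noise and a random rotation. DA, FA and
digitization noise act on an absolute (image-unit) scale, so relative
asymmetry grows as segments get smaller — the generative version of the
negative size–asymmetry coupling in real data. All randomness derives
from one master seed through per-level sub-streams, so changing segment
counts does not shift plant-level draws and identical seeds give
bit-identical data.

`studyLikeSpec()` fixes the design at 2 localities x 48 plants with a
deterministic vector of segments per plant (median 9.5, 982 segments in
total, reproducing the degrees-of-freedom column 1, 94, 886, 96, 886,
1964 of the full nested model) and locality A's median size 18% below
locality B's. The default magnitudes were calibrated once to the
variance decomposition typical of field data of this kind — per-record
shape variance of roughly 0.006 allometric, 0.002 between plants, 0.009
between segments after size adjustment, 0.0004 DA, 0.003 FA and 0.0006
digitization error — and then frozen. A study-like run lands close to
that regime (PC1 about 66%, allometry 28–30% of shape variance, FA
about 7 times the digitization error, DA F around 1.5–1.8, and the
locality effect collapsing to F near 1 after size adjustment).

What the generator does *not* emulate: digitization artifacts that are
correlated along the outline (our noise is white), non-linear
allometry, plant-level correlation between size and asymmetry beyond
the 1/size scaling, and any ecological covariate structure. Passing
tests therefore validate the geometry and the inference machinery, not
any biological claim about real populations.

## Numerical choices and problem sizes

* GPA tolerance `1e-7` on consensus displacement, max 100 iterations;
  non-convergence returns the best iterate with a warning and a
  diagnostics flag.
* Rotations come from the closed-form SVD solution with the determinant
  constrained to +1; reflections enter only via `reflectRelabel`.
* The TPS system is solved densely; duplicate reference points are a
  kernel error.
* Sliding: 3 cycles, kernel and consensus refreshed per cycle;
  `min_pd`'s neighbor-overtaking events are counted per cycle.
* Axis classification threshold 0.99 on the score-mirroring
  correlation.
* Bootstrap CIs are percentile intervals (type-7 quantiles).
* Test and acceptance runs use reduced problem sizes chosen to keep the
  whole suite in the low minutes: 20–30-point outlines and 2x3 to 2x8
  plant designs for unit and property tests, 220 simulations at 99
  permutations for the null-calibration check, and the full 90-point,
  3928-record study-like design for the df/bookkeeping acceptance test
  and the acceptance script.

## Limitations

2D closed outlines with a single fixed landmark only; no 3D or surface
semilandmarks, no missing-point estimation, no mixed-model (REML)
variance components — the design is balanced in side and replicate by
construction, and unbalanced segment counts are handled exactly by the
sequential decomposition. The `min_pd` treatment is provided for
methodological comparison, not for downstream inference.
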