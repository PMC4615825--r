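---
title: "Measuring myelinated cortical thickness: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring myelinated cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcthick)
```

## The model

Intracortical myelin concentrates in the deep cortical layers. On a
heavily T1-weighted image with sufficient intracortical contrast, the
cortical depth therefore splits into two intensity bands, and the
cerebrum can be modelled as three nested tissue compartments ordered by
increasing T1-weighted intensity: lightly myelinated gray matter (GM),
heavily myelinated gray matter (mGM) and white matter (WM). `mcthick`
turns that intensity model into a morphological one. With signed
distance levelsets $\varphi$ of the three nested boundaries (CSF/GM,
GM/mGM, mGM/WM; positive inside the enclosed region), thickness at the
pial surface is

$$G = \varphi_{CSF/GM} - \varphi_{GM/mGM}, \qquad
  T = \varphi_{CSF/GM} - \varphi_{mGM/WM}, \qquad
  M = T - G, \qquad P = M/T.$$

$M = T - G$ holds exactly by construction; $P$ is set to 0 where $T = 0$.
The model's central assumption — that a discrete GM/mGM boundary exists
and is imageable at ~1 mm — is an approximation: histology shows regions
(sulcal fundi, transitional cortex) where the myelinated band thins or
grades smoothly, and there this two-band description is simplistic. The
package measures the model; it cannot validate it against tissue.

## Pipeline stages and their parameters

**Ratio image.** `compute_ratio_image()` divides T1w by median-filtered
PDw. The kernel default is 5 mm (a 5×5×5 voxel window at 1 mm), large
enough to erase anatomy from the PDw denominator but small relative to
the receive-field variation it corrects; filtering uses symmetric edge
reflection and is applied to the full volume before masking, because the
filter semantics should not depend on an arbitrary mask boundary. Only
the PDw image is filtered. Background is forced to zero: the raw ratio
is noise-over-noise outside the head.

**Fuzzy segmentation.** `fcm_segment()` minimizes the fuzzy c-means
objective with an optional Pham-style neighbourhood penalty
(weight `beta`, 6-neighbourhood, fuzziness `q`, defaults `q = 2`,
`beta = 0`). With `beta = 0` the algorithm is plain FCM, which is the
verifiable limit the tests exploit (a brute-force minimizer of the
reduced objective cross-checks it on tiny instances). Centroids are
initialized at the 25th/50th/75th masked-intensity percentiles —
deterministic, so repeated runs are identical; if strongly unbalanced
class volumes collapse two percentiles onto one value, the
initialization falls back to evenly spaced centroids. Classes are
sorted by centroid, so GM is always the dimmest and WM the brightest
class. Convergence is declared on a relative objective change below
`tol` (default 1e-8); non-convergence at `max_iter` warns and returns
the best iterate, and the per-iteration objective trace is kept in the
result for QC.

**Nested labels.** `build_nested_labels()` thresholds memberships
sequentially, innermost first, with *strict* inequalities: WM > 0.1,
then mGM > 0.5, then GM > 0.5; leftover mask voxels are background
(CSF-side). Strictness matters only on ties and the method's own
description mixes "0.5 or greater" with "above 0.5"; we chose strict
consistently. The deliberately permissive WM cutoff compensates the
partial-volume shrinkage of thin gyral WM blades that a symmetric 0.5
cut produces when a third class competes at the boundary; because the
fuzzy classification itself is untouched, the change moves only the WM
boundary. That invariance is exact whenever every voxel with WM
membership in (0.1, 0.5] also has mGM membership above 0.5 — true of
interface voxels flanking WM — but a voxel mixed almost exactly half
mGM/half WM (memberships ≈ 0.47/0.47) can enter the inner region only
under the loose cutoff, so on heavily partial-volumed data the GM/mGM
boundary may shift at isolated ambiguous voxels. The test suite checks
the invariance where it is exact.

**Cleanup.** WM is reduced to its largest 26-connected component
(fragments demote to mGM; ties go to the component appearing first in
column-major scan order). The GM/mGM boundary is smoothed by
opening-then-closing with a Euclidean ball of 2 mm diameter (radius
≥ 1 voxel) — the reference workflow used an interactive tool whose
smoothing semantics are unpublished, so opening-closing is our explicit,
idempotent stand-in — then WM is re-unioned and the result clipped to
the cortex so nesting is preserved exactly. Finally inner tissue is
removed from the pial surface by intersecting with the 1-voxel
6-connectivity erosion of the cortex. Connectivity conventions are
fixed: 26 for components, 6 for erosion.

**Levelsets and thickness.** `signed_distance()` computes an exact
Euclidean distance transform (separable lower-envelope algorithm,
anisotropic-safe, with nearest-site propagation) between voxel centres,
then shifts by half the smallest voxel dimension so the zero level sits
on the voxel faces between region and background. Positive-inside is
chosen so the formulas above give positive thicknesses at the pial
surface. The grid border is deliberately *not* a boundary, which makes
the levelset of a complement region the exact negation — convenient for
testing and harmless for interior anatomy. Pial voxels are those with
$|\varphi_{CSF/GM}|$ below half the voxel diagonal; whether thickness
should be evaluated only at exact zero-crossings or in this near-boundary
band is an interpretation, and the band was chosen because it is
well-populated on digital surfaces of any orientation. Values propagate
to the rest of the cortex by nearest pial voxel; non-cortex voxels are
`NA` in memory and 0-plus-validity-mask on disk. Negative M (possible
when segmentation pathology breaks nesting) is counted in the QC summary
but never clamped, so problems remain visible.

## The phantom generator

`generate_phantom()` emulates what the pipeline actually consumes: a
cerebrum-masked ratio image with three laminar classes (default
intensities 1/2/3), additive Gaussian noise and a smooth multiplicative
bias field. The defaults are the reference validation conditions: a 64³,
1 mm isotropic spherical shell with radii 24/20/17 mm — truth T = 7,
G = 4, M = 3 mm, the right order of magnitude for cortex while thick
enough to be resolvable at 1 mm — and noise sd of 5% of the unit class
contrast, a conservative figure for the high-SNR averaged acquisitions
this method targets. Noise is Gaussian rather than Rician because the
inputs are high-SNR magnitude sums where the Rician correction is
negligible. The bias field is a degree-2 polynomial in normalized
coordinates scaled to a peak fractional amplitude, smooth enough that
the ratio construction should cancel it; `generate_paired_t1w_pdw()`
produces T1w/PDw pairs sharing one bias field to exercise exactly that.
Partial volume can be simulated by 3× supersampling and box-averaging
(`supersample = TRUE`), off by default.

What the phantoms do *not* emulate: realistic gyrification (the folded
shell only undulates the surfaces), partial-volume mixtures at default
settings, Rician tails, registration error, or regionally varying layer
thickness. Passing phantom tests therefore demonstrates correctness of
the measurement machinery — segmentation, distances, statistics — not
performance on real anatomy.

`make_cohort()` mirrors a small case–control imaging study: per-subject
multiplicative jitter (default sd 2%) on the layer thicknesses, and a
fractional decrease of G and/or M in the case group. Group sizes default
to 10 + 10, the scale of a pilot clinical comparison.

## Statistics

`group_compare()` runs one-way ANOVA with Tukey HSD, gated (warn, not
abort) by Anderson–Darling normality per group and Levene's variance
test — Levene chosen for robustness since the homogeneity test in the
reference workflow is unnamed; with fewer than 8 subjects per group the
normality check falls back to Shapiro–Wilk, which remains defined at
small n. With two groups the ANOVA F equals the squared two-sample t
statistic, which is exposed in the output. No multiple-testing
correction is applied across metrics or ROIs by default, matching the
workflow the package reproduces; users can correct externally.
`detectable_effect()` is the standard noncentral-t minimal detectable
difference (via `power.t.test`, two-sided, default α = 0.05 and power
0.8) using the control-group sd, expressed as percent of the control
mean. `average_atlas()` averages co-registered maps voxelwise and keeps
voxels defined in at least half the subjects; registration itself is out
of scope — maps must already share a grid, and every multi-volume
operation verifies grid compatibility (shape, spacing, affine within
1e-4 relative) instead of resampling silently.

## Numerical choices and degenerate inputs

* Distances are in mm throughout, computed from the voxel spacing;
  anisotropic grids are supported, though the half-voxel levelset offset
  uses the smallest spacing and is exact only for isotropic grids.
* Boundary placement on voxel faces shifts each absolute levelset by up
  to half a voxel; thickness differences cancel most of it, leaving a
  sub-voxel negative bias on T and G (≈ 0.3 mm on the 1 mm reference
  sphere) and an almost unbiased M.
* Constant images are rejected by the clustering (degenerate); empty or
  grid-filling regions are rejected by the distance transform; masks
  must be exactly binary and non-empty; NaN/Inf voxels fail at load.
* Thresholds must lie strictly inside (0, 1). Membership ties at a
  centroid produce exact one-hot memberships (zero-distance handling).
* A cortex one voxel thick still yields finite, non-negative T.

## Problem sizes used in validation

The test-suite and acceptance computations run the full pipeline on 64³
phantoms (seconds per run), exactness checks on 20³–34³ volumes, and the
statistics calibration at summary level: 400 null cohorts for the
type-I error rate, 200 cohorts at the injected minimal detectable
effect for empirical power, and 10⁴-replicate Monte-Carlo power curves
against the closed-form solution. These sizes give Monte-Carlo standard
errors comfortably below the tolerances being checked while keeping a
complete validation run around a minute.

## Known limitations

* The two-band cortical model ignores regionally diffuse myelination
  gradients; where the GM/mGM interface is not sharp, M is a model
  quantity, not an anatomical one.
* Partial voluming at 1 mm biases the mGM/WM boundary; the loose WM
  threshold is a blunt correction, and proper partial-volume modelling
  is future work.
* Skull stripping, cerebrum labelling, topology correction and
  registration are upstream: the package expects a cerebrum mask (or
  phantom) and co-registered grids.
* Surface meshing, inflation and vertexwise statistics are out of
  scope; outputs are voxel maps and tables.
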