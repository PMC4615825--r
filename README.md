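# mcthick — myelinated cortical thickness from high-contrast MRI

The deeper layers of the cerebral cortex (roughly layers IV–VI) carry most
of the cortex's myelinated axons, and on heavily T1-weighted MRI they are
bright enough to distinguish from the lightly myelinated superficial
layers. `mcthick` exploits that contrast to split the familiar total
cortical thickness measurement into morphological components: instead of
tracking a myelin-sensitive MR signal at some fixed cortical depth — which
becomes ambiguous when the cortex itself thins — it measures *how thick*
the heavily myelinated portion of the cortex is. The package is aimed at
neuroimaging researchers studying intracortical myelin in development,
ageing and disease (e.g. mood disorders or schizophrenia, where
oligodendrocyte and myelin deficits are suspected) at clinically
realistic field strengths and ~1 mm resolution.

## Method

Starting from a cerebrum-masked **ratio image** (the high-contrast
T1-weighted volume divided by a median-filtered proton-density-weighted
volume, which cancels receive-field inhomogeneity), the pipeline:

1. **Segments** the cerebrum into three intensity classes — lightly
   myelinated gray matter (GM), heavily myelinated gray matter (mGM) and
   white matter (WM) — with fuzzy c-means clustering, optionally
   spatially regularized by a 6-neighbourhood membership penalty.
2. **Binarizes** the memberships into nested regions with sequential
   strict thresholds (WM > 0.1, then mGM > 0.5, then GM > 0.5; the
   permissive WM cutoff counteracts partial-volume shrinkage of thin
   gyral WM blades and moves only the WM boundary), keeps the largest
   26-connected WM component, smooths the GM/mGM boundary with a 2 mm
   morphological kernel, and strips inner-tissue voxels off the pial
   surface.
3. **Measures thickness** from signed Euclidean distance levelsets
   φ of the three nested boundaries (positive inside), evaluated at the
   pial (CSF/GM) surface:

       G = φ_CSF/GM − φ_GM/mGM        (unmyelinated thickness)
       T = φ_CSF/GM − φ_mGM/WM        (total cortical thickness)
       M = T − G                      (myelinated thickness)
       P = M / T                      (proportional myelinated thickness)

   Values are propagated from the pial band to the whole cortex by
   nearest-pial-voxel assignment and embedded in full-size volumes.

A synthetic-phantom module generates cerebrum-masked laminar phantoms
(spherical shell, folded shell, slab) with known ground-truth T/G/M/P,
Gaussian noise and a smooth multiplicative bias field, so the whole
pipeline is validated end to end without scan data. A statistics layer
provides ROI summaries, voxelwise atlas averaging, group comparison
(one-way ANOVA + Tukey HSD with Anderson–Darling normality and Levene
variance checks) and the minimal-detectable-effect power analysis.

## Worked example

Measure thickness on the default validation phantom (64³ voxels at 1 mm,
spherical shell with pial / GM–mGM / mGM–WM radii 24 / 20 / 17 mm, so the
truth is T = 7, G = 4, M = 3 mm, P = 3/7 ≈ 0.43; noise sd 5% of the class
contrast):

```r
library(mcthick)

ph  <- generate_phantom(phantom_spec(seed = 42))
mem <- fcm_segment(ph$ratio, ph$truth$mask)
mem
#> <membership_set> 3 classes, centroids: 1.00037, 2.00007, 3.00065
#>   4 iterations, converged: TRUE, final objective 144.436

labels <- build_nested_labels(mem)      |>
  keep_largest_component()              |>
  smooth_inner_boundary()               |>
  strip_pial_voxels()
maps <- cortical_thickness(labels)
maps
#> <thickness_maps> pial-surface means (mm; P unitless):
#>     T     G     M     P
#> 6.691 3.742 2.949 0.441
#>   12000 pial voxels, 0 negative-M, 0 negative-G
```

The recovered pial-surface means are within a third of a voxel of the
truth: the ~0.3 mm shortfall in T and G is boundary digitization on a
1 mm grid, and M — the difference of two nearby boundaries — is nearly
unbiased. ROI statistics work on the same maps:

```r
roi <- roi_extract(maps, array(TRUE, dim(maps$T$data)),
                   subject = "phantom01", group = "control")
round(roi[, c("n_voxels", "mean_T", "mean_G", "mean_M", "mean_P")], 3)
#>   n_voxels mean_T mean_G mean_M mean_P
#> 1    64024  6.518  3.567  2.951  0.453
```

`run_pipeline()` (or the `exec/mct` command-line script with subcommands
`phantom`, `preprocess`, `segment`, `thickness`, `roi-stats`, `run`)
orchestrates the same stages with content-hash skipping, JSON provenance
and NIfTI outputs.

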