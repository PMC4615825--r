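#' Binarize tissue memberships into nested labels
#'
#' Builds hard labels by sequential, exclusive thresholding, innermost
#' class first: WM voxels are those with WM membership strictly above
#' `wm_threshold`; of the remainder, mGM voxels are those with mGM
#' membership strictly above `mgm_threshold`; of the rest, GM voxels have
#' GM membership strictly above `gm_threshold`. Mask voxels passing no
#' threshold become background (they fall on the CSF side of the pial
#' boundary). The permissive default WM threshold of 0.1 counteracts
#' partial-volume shrinkage of thin gyral white matter blades; because the
#' fuzzy classification itself is unchanged, lowering it moves only the
#' mGM/WM boundary and leaves the GM/mGM boundary untouched.
#'
#' @param m A `membership_set` from [fcm_segment()] (3 classes).
#' @param wm_threshold,mgm_threshold,gm_threshold Strict membership
#'   thresholds in (0, 1); defaults 0.1 / 0.5 / 0.5.
#' @return An object of class `nested_labels`: a label volume over
#'   \{0 = background, 1 = GM, 2 = mGM, 3 = WM\} with accessors
#'   [region_wm()], [region_inner()], [region_cortex()].
#' @export
build_nested_labels <- function(m, wm_threshold = 0.1, mgm_threshold = 0.5,
                                gm_threshold = 0.5) {
  stopifnot(inherits(m, "membership_set"))
  if (m$params$n_classes != 3)
    stop("nested labels are defined for 3 classes (GM, mGM, WM)")
  thr <- c(wm_threshold, mgm_threshold, gm_threshold)
  if (any(thr <= 0) || any(thr >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  u_gm <- m$u$gm$data; u_mgm <- m$u$mgm$data; u_wm <- m$u$wm$data
  msk <- m$mask
  lab <- array(0L, dim(u_gm))
  wm <- msk & !is.na(u_wm) & u_wm > wm_threshold
  mgm <- msk & !wm & !is.na(u_mgm) & u_mgm > mgm_threshold
  gm <- msk & !wm & !mgm & !is.na(u_gm) & u_gm > gm_threshold
  lab[gm] <- 1L; lab[mgm] <- 2L; lab[wm] <- 3L
  new_nested_labels(lab, m$u$gm$spacing, m$u$gm$affine)
}

new_nested_labels <- function(lab, spacing, affine) {
  structure(list(labels = vol3d(lab, spacing = spacing, affine = affine,
                                unit = "label"),
                 spacing = spacing, affine = affine),
            class = "nested_labels")
}

#' @export
print.nested_labels <- function(x, ...) {
  l <- x$labels$data
  cat(sprintf("<nested_labels> GM %d | mGM %d | WM %d voxels (bg %d)\n",
              sum(l == 1), sum(l == 2), sum(l == 3), sum(l == 0)))
  invisible(x)
}

#' Nested tissue regions
#'
#' The three nested regions derived from a label volume: white matter
#' (`region_wm`), white matter plus heavily myelinated gray matter
#' (`region_inner`, bounded by the GM/mGM interface), and the full cortex
#' plus white matter (`region_cortex`, bounded by the pial surface).
#'
#' @param x A `nested_labels` object.
#' @return Logical 3D array.
#' @export
region_wm <- function(x) x$labels$data >= 3L

#' @rdname region_wm
#' @export
region_inner <- function(x) x$labels$data >= 2L

#' @rdname region_wm
#' @export
region_cortex <- function(x) x$labels$data >= 1L

# nesting is structural (label >= k), asserted for safety after each edit
assert_nesting <- function(x) {
  stopifnot(all(region_wm(x) <= region_inner(x)),
            all(region_inner(x) <= region_cortex(x)))
  invisible(x)
}

#' Restrict white matter to its largest connected component
#'
#' Labels the WM region with 26-connectivity and keeps only the largest
#' component; disconnected fragments (typically partial-volume islands) are
#' demoted to mGM so nesting is preserved. Ties are broken in favour of the
#' component containing the smallest voxel index in column-major scan
#' order.
#'
#' @param labels A `nested_labels` object with non-empty WM.
#' @return Updated `nested_labels`.
#' @export
keep_largest_component <- function(labels) {
  stopifnot(inherits(labels, "nested_labels"))
  wm <- region_wm(labels)
  if (!any(wm)) stop("WM region is empty")
  comp <- label_components(wm)
  sizes <- tabulate(comp[wm])
  keep <- which.max(sizes)  # first maximum = smallest scan-order seed voxel
  lab <- labels$labels$data
  lab[wm & comp != keep] <- 2L
  new_nested_labels(lab, labels$spacing, labels$affine)
}

#' Morphologically smooth the GM/mGM boundary
#'
#' Replaces the inner region (mGM + WM) by its morphological
#' opening-then-closing with a Euclidean ball structuring element of
#' diameter `kernel_mm` (voxel radius at least 1), which removes
#' sub-kernel protrusions and fills sub-kernel indentations of the GM/mGM
#' interface. The WM region is re-unioned afterwards and the result is
#' clipped to the cortex, so the nesting WM within inner within cortex is
#' preserved exactly.
#'
#' @param labels A `nested_labels` object with non-empty inner region.
#' @param kernel_mm Ball diameter in mm (default 2).
#' @return Updated `nested_labels`.
#' @export
smooth_inner_boundary <- function(labels, kernel_mm = 2) {
  stopifnot(inherits(labels, "nested_labels"))
  inner <- region_inner(labels)
  if (!any(inner)) stop("inner (mGM + WM) region is empty")
  offs <- ball_offsets_mm(kernel_mm / 2, labels$spacing)
  sm <- binary_close(binary_open(inner, offs), offs)
  sm <- (sm & region_cortex(labels)) | region_wm(labels)
  if (!any(sm)) stop("morphological smoothing emptied the inner region")
  lab <- labels$labels$data
  lab[lab == 2L & !sm] <- 1L            # smoothed away -> GM
  lab[lab == 1L & sm] <- 2L             # filled in -> mGM
  new_nested_labels(lab, labels$spacing, labels$affine)
}

#' Strip inner-tissue voxels from the pial surface
#'
#' Intersects the inner region with the 1-voxel (6-connectivity) erosion of
#' the cortex region, so that no mGM/WM voxel lies on the outer (pial)
#' boundary of the cortex; demoted voxels become GM. This keeps the
#' GM/mGM levelset strictly interior to the pial levelset.
#'
#' @param labels A `nested_labels` object with non-empty cortex.
#' @return Updated `nested_labels`.
#' @export
strip_pial_voxels <- function(labels) {
  stopifnot(inherits(labels, "nested_labels"))
  cortex <- region_cortex(labels)
  if (!any(cortex)) stop("cortex region is empty")
  er <- binary_erode(cortex, offsets_face6())
  if (!any(er)) stop("1-voxel erosion emptied the cortex region")
  lab <- labels$labels$data
  demote <- region_inner(labels) & !er
  lab[demote] <- 1L
  new_nested_labels(lab, labels$spacing, labels$affine)
}
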