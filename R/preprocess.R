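#' 3D median filter with a kernel given in millimetres
#'
#' The mm kernel is converted per axis to the nearest odd voxel window
#' (minimum 1), so a 5 mm kernel on a 1 mm grid uses a 5 x 5 x 5 voxel
#' window. Volume edges are handled by symmetric reflection.
#'
#' @param v [vol3d] to filter.
#' @param kernel_mm Kernel size in mm; scalar or length-3.
#' @return Filtered [vol3d].
#' @export
median_filter_mm <- function(v, kernel_mm = 5) {
  if (!is_vol3d(v)) v <- vol3d(v)
  kernel_mm <- rep_len(as.numeric(kernel_mm), 3L)
  if (any(!is.finite(kernel_mm)) || any(kernel_mm <= 0))
    stop("`kernel_mm` must be strictly positive")
  if (any(kernel_mm < v$spacing))
    stop("`kernel_mm` must be >= voxel spacing on every axis")
  win <- kernel_window_voxels(kernel_mm, v$spacing)
  out <- median_filter3d_cpp(v$data, dim(v$data), win)
  vol3d(out, spacing = v$spacing, affine = v$affine, unit = v$unit)
}

# nearest odd integer >= 1 to kernel_mm / spacing
kernel_window_voxels <- function(kernel_mm, spacing) {
  x <- kernel_mm / spacing
  w <- 2L * as.integer(round((x - 1) / 2)) + 1L
  pmax(w, 1L)
}

#' Build the bias-corrected ratio image
#'
#' Divides the high-contrast T1-weighted volume by a median-filtered
#' proton-density-weighted volume and restricts the result to the cerebrum
#' mask. Because receive-field (B1) inhomogeneity multiplies both inputs by
#' the same smooth field, and the median filter leaves a locally constant
#' field unchanged, the division cancels the bias while keeping the
#' T1-weighted tissue contrast. Only the PDw volume is filtered; the T1w
#' volume enters unfiltered.
#'
#' Background voxels (outside the mask) are set to 0: the raw ratio is
#' ill-behaved where the denominator is near noise level.
#'
#' @param t1w,pdw [vol3d] inputs on the same grid.
#' @param mask Cerebrum mask (`mask_vol3d` or coercible).
#' @param kernel_mm Median filter kernel in mm (default 5).
#' @param eps Division guard: filtered-PDw values at mask voxels must exceed
#'   `eps`. Default `1e-6 *` median filtered-PDw over the mask.
#' @return [vol3d] ratio image, zero outside the mask, unit `"ratio"`.
#' @export
compute_ratio_image <- function(t1w, pdw, mask, kernel_mm = 5, eps = NULL) {
  if (!is_vol3d(t1w)) t1w <- vol3d(t1w)
  if (!is_vol3d(pdw)) pdw <- vol3d(pdw)
  if (!inherits(mask, "mask_vol3d")) mask <- as_mask(mask, spacing = t1w$spacing,
                                                    affine = t1w$affine)
  stop_if_incompatible(t1w, pdw, mask, what = "t1w/pdw/mask")
  filt <- median_filter_mm(pdw, kernel_mm)
  m <- mask_logical(mask)
  fm <- filt$data[m]
  if (is.null(eps)) eps <- 1e-6 * stats::median(fm)
  bad <- sum(fm <= eps)
  if (bad > 0)
    stop("filtered PDw is <= ", format(eps), " at ", bad,
         " mask voxel(s); ratio undefined there")
  out <- array(0, dim(t1w$data))
  out[m] <- t1w$data[m] / fm
  vol3d(out, spacing = t1w$spacing, affine = t1w$affine, unit = "ratio")
}
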