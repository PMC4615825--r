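#' Signed Euclidean distance levelset of a region
#'
#' Computes an exact Euclidean signed distance function for a voxelized
#' region: positive inside the region, negative outside, in mm. Distances
#' are computed between voxel centres with an exact (Felzenszwalb)
#' transform and then shifted by half a voxel (`0.5 * min(spacing)`)
#' towards the boundary, which places the zero level on the voxel faces
#' between region and non-region voxels. The grid border is not treated as
#' a boundary, so the levelset of the complement region is the exact
#' voxelwise negation.
#'
#' The "positive inside" convention is what makes the levelset-difference
#' thickness formulas return positive thicknesses at the pial surface:
#' at a pial voxel the pial levelset is near 0 while the levelsets of the
#' deeper (nested) boundaries are negative.
#'
#' @param region Logical 3D array, or a [vol3d]/`mask_vol3d`; must be
#'   non-empty and not cover the whole grid.
#' @param spacing Voxel spacing in mm (taken from `region` if a `vol3d`).
#' @param affine Optional affine carried to the output.
#' @param boundary Free-text name of the boundary (e.g. `"csf_gm"`),
#'   stored on the result.
#' @return An object of class `c("levelset", "vol3d")` with unit `"mm"`.
#' @export
signed_distance <- function(region, spacing = c(1, 1, 1), affine = NULL,
                            boundary = "boundary") {
  if (is_vol3d(region)) {
    spacing <- region$spacing
    affine <- region$affine
    region <- region$data > 0.5
  }
  storage.mode(region) <- "logical"
  n_in <- sum(region)
  if (n_in == 0) stop("region is empty: signed distance undefined")
  if (n_in == length(region))
    stop("region covers the whole grid: signed distance undefined")
  d_bg <- edt_cpp(!region, dim(region), spacing)$dist  # to nearest outside voxel
  d_fg <- edt_cpp(region, dim(region), spacing)$dist   # to nearest inside voxel
  off <- 0.5 * min(spacing)
  phi <- ifelse(region, d_bg - off, -(d_fg - off))
  out <- vol3d(phi, spacing = spacing, affine = affine, unit = "mm")
  class(out) <- c("levelset", class(out))
  attr(out, "boundary") <- boundary
  out
}

# distance (mm) from every voxel to the nearest voxel of `sites`,
# with the nearest site's linear index (feature transform)
nearest_site <- function(sites, spacing) {
  edt_cpp(sites, dim(sites), spacing)
}
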