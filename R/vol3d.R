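#' @useDynLib mcthick, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a 3D volume
#'
#' `vol3d` is the package's lightweight container for a scalar 3D grid: a
#' numeric array plus the voxel spacing in mm and a 4x4 voxel-to-world affine.
#' All physical distances downstream are computed from `spacing`, so
#' anisotropic grids are handled correctly.
#'
#' @param data 3D numeric or logical array. `NA` is permitted (used as the
#'   "undefined" sentinel in thickness maps) but `NaN`/`Inf` are rejected.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive and finite.
#' @param affine 4x4 voxel-to-world matrix. Defaults to a diagonal scaling by
#'   `spacing` (0-based voxel index convention).
#' @param unit Free-text unit of the voxel values, e.g. `"intensity"`,
#'   `"mm"`, `"probability"`.
#' @return An object of class `vol3d` with fields `data`, `spacing`,
#'   `affine`, `unit`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), affine = NULL,
                  unit = "intensity") {
  if (is.logical(data)) storage.mode(data) <- "double"
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array (got ", length(dim(data)), " dimensions)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  if (any(is.nan(data)) || any(is.infinite(data)))
    stop("volume contains NaN or Inf voxels")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 unit = unit),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, unit '%s'\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$unit))
  v <- x$data[!is.na(x$data)]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], %d NA voxels\n", min(v), max(v),
                sum(is.na(x$data))))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

is_vol3d <- function(x) inherits(x, "vol3d")

# accept a vol3d or a bare array (used throughout so helpers compose)
as_array3d <- function(x) {
  if (is_vol3d(x)) x$data else x
}

#' Coerce a volume to a binary mask
#'
#' Checks that voxel values are exactly 0/1 (within `tol`) and that the mask
#' is non-empty, then returns a `vol3d` with logical-like 0/1 payload and
#' class `mask_vol3d`.
#'
#' @param v A `vol3d` (or 3D array).
#' @param spacing,affine Used when `v` is a bare array.
#' @param tol Tolerance for treating stored values as 0/1 (handles float
#'   round-trip of label files).
#' @return `vol3d` of 0/1 values, class `c("mask_vol3d", "vol3d")`.
#' @export
as_mask <- function(v, spacing = c(1, 1, 1), affine = NULL, tol = 1e-6) {
  if (!is_vol3d(v)) v <- vol3d(v, spacing = spacing, affine = affine,
                               unit = "binary")
  x <- v$data
  if (any(abs(x) > tol & abs(x - 1) > tol, na.rm = TRUE))
    stop("mask contains values other than 0 and 1")
  if (any(is.na(x))) stop("mask contains NA voxels")
  x <- ifelse(abs(x - 1) <= tol, 1, 0)
  if (sum(x) < 1) stop("mask is empty (no foreground voxel)")
  out <- vol3d(x, spacing = v$spacing, affine = v$affine, unit = "binary")
  class(out) <- c("mask_vol3d", class(out))
  out
}

mask_logical <- function(m) as_array3d(m) > 0.5

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file (plain or gzipped) into a [vol3d]. 4D inputs are
#' rejected unless the 4th dimension is a singleton; `NaN`/`Inf` voxels are
#' an error so that downstream arithmetic never propagates them silently.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param unit Unit string recorded on the returned volume.
#' @return A [vol3d].
#' @export
read_volume <- function(path, unit = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))  # strip header attributes
  d <- dim(a)
  if (length(d) == 4L) {
    if (d[4] == 1L) {
      a <- array(a, d[1:3])
    } else {
      stop("4D input with ", d[4], " volumes is not supported; ",
           "supply one 3D volume per file")
    }
  }
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)), " dimensions")
  if (any(is.na(a)) || any(is.infinite(a)))
    stop("volume contains NaN/Inf voxels: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  vol3d(a, spacing = sp, affine = aff, unit = unit)
}

#' Read a NIfTI label/mask file as a binary mask
#'
#' @inheritParams read_volume
#' @return A `mask_vol3d`.
#' @export
read_mask <- function(path) {
  as_mask(read_volume(path, unit = "binary"))
}

#' Write a volume to NIfTI
#'
#' Float32 payloads round-trip bit-exactly; spacing and affine (sform/qform)
#' are preserved. `NA` voxels are written as `na_fill` (the in-memory
#' "undefined" sentinel has no NIfTI counterpart).
#'
#' @param v A [vol3d] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, default `"float"`.
#' @param na_fill Value written in place of `NA` voxels.
#' @param description Optional string stored in the NIfTI `descrip` header
#'   field (run provenance).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float", na_fill = 0,
                         description = NULL) {
  if (!is_vol3d(v)) v <- vol3d(v)
  a <- v$data
  a[is.na(a)] <- na_fill
  img <- RNifti::asNifti(a, datatype = datatype)
  img$pixdim <- c(-1, v$spacing, 0, 0, 0, 0)
  aff <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  if (!is.null(description))
    img$descrip <- substr(description, 1L, 79L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Test whether two volumes live on the same grid
#'
#' Two volumes are grid-compatible iff their array shapes match exactly and
#' their spacings and affines agree within a relative tolerance. Every
#' multi-input operation in the package calls this first and refuses to run
#' on incompatible grids rather than silently resampling.
#'
#' @param a,b [vol3d] objects.
#' @param tol Relative tolerance (default 1e-4).
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_compatible <- function(a, b, tol = 1e-4) {
  if (!is_vol3d(a) || !is_vol3d(b)) stop("inputs must be vol3d objects")
  if (!identical(dim(a$data), dim(b$data))) return(FALSE)
  rel <- function(x, y) abs(x - y) / pmax(abs(x), abs(y), 1)
  if (any(rel(a$spacing, b$spacing) > tol)) return(FALSE)
  if (any(rel(a$affine, b$affine) > tol)) return(FALSE)
  TRUE
}

stop_if_incompatible <- function(..., what = "inputs") {
  vols <- list(...)
  for (i in seq_along(vols)[-1]) {
    if (!check_grid_compatible(vols[[1]], vols[[i]]))
      stop(what, " are not grid-compatible (shape/spacing/affine mismatch); ",
           "resample upstream before calling mcthick")
  }
  invisible(TRUE)
}
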