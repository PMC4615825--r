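#' Thickness metrics from nested boundary levelsets
#'
#' Evaluates, at each pial-surface voxel, the four thickness metrics
#' defined by differences of signed-distance levelsets of the nested
#' tissue boundaries:
#' \deqn{G = \varphi_{CSF/GM} - \varphi_{GM/mGM}}
#' \deqn{T = \varphi_{CSF/GM} - \varphi_{mGM/WM}}
#' \deqn{M = T - G}
#' \deqn{P = M / T \quad (P = 0 \text{ where } T = 0)}
#' where each \eqn{\varphi} is positive inside its enclosed region. Pial
#' voxels are those with \eqn{|\varphi_{CSF/GM}|} below half the voxel
#' diagonal. The identity `T = G + M` holds exactly by construction.
#'
#' Values are then propagated from the pial band to every cortex voxel by
#' nearest-pial-voxel assignment and embedded in full-size volumes;
#' non-cortex voxels carry `NA`. Negative `M` values (possible under
#' segmentation pathology) are counted in the QC summary but deliberately
#' not clamped.
#'
#' @param phi_csf_gm,phi_gm_mgm,phi_mgm_wm Levelsets from
#'   [signed_distance()] of the cortex, inner (mGM + WM) and WM regions
#'   respectively; grid-compatible.
#' @return Object of class `thickness_maps`: [vol3d] fields `T`, `G`,
#'   `M` (mm) and `P` (dimensionless), logical `pial` and `cortex`
#'   masks, and a `qc` list (pial voxel count, negative-M/G counts,
#'   pial-surface summary statistics).
#' @export
thickness_at_pial <- function(phi_csf_gm, phi_gm_mgm, phi_mgm_wm) {
  stop_if_incompatible(phi_csf_gm, phi_gm_mgm, phi_mgm_wm,
                       what = "levelsets")
  sp <- phi_csf_gm$spacing
  half_diag <- sqrt(sum(sp^2)) / 2
  pc <- phi_csf_gm$data
  pg <- phi_gm_mgm$data
  pw <- phi_mgm_wm$data
  pial <- abs(pc) < half_diag
  if (!any(pial)) stop("no pial voxels found (empty pial band)")
  cortex <- pc > 0 | pial

  g_p <- pc[pial] - pg[pial]
  t_p <- pc[pial] - pw[pial]
  m_p <- t_p - g_p
  p_p <- ifelse(t_p == 0, 0, m_p / t_p)

  n_neg_g <- sum(g_p < 0)
  if (n_neg_g > 0.01 * length(g_p))
    warning("G < 0 at ", n_neg_g, " of ", length(g_p),
            " pial voxels: boundary regions are not properly nested")

  # propagate: every cortex voxel inherits the value of its nearest pial voxel
  ft <- nearest_site(pial, sp)$nearest
  idx_p <- which(pial)
  lut <- integer(length(pc))
  lut[idx_p] <- seq_along(idx_p)
  src <- lut[ft[cortex]]

  embed <- function(vals, unit) {
    a <- array(NA_real_, dim(pc))
    a[cortex] <- vals[src]
    vol3d(a, spacing = sp, affine = phi_csf_gm$affine, unit = unit)
  }
  maps <- list(T = embed(t_p, "mm"), G = embed(g_p, "mm"),
               M = embed(m_p, "mm"), P = embed(p_p, "ratio"))
  qc <- list(n_pial = length(idx_p),
             n_negative_M = sum(m_p < 0),
             n_negative_G = n_neg_g,
             pial_mean = c(T = mean(t_p), G = mean(g_p), M = mean(m_p),
                           P = mean(p_p)),
             pial_sd = c(T = stats::sd(t_p), G = stats::sd(g_p),
                         M = stats::sd(m_p), P = stats::sd(p_p)))
  structure(c(maps, list(pial = pial, cortex = cortex, qc = qc)),
            class = "thickness_maps")
}

#' @export
print.thickness_maps <- function(x, ...) {
  cat("<thickness_maps> pial-surface means (mm; P unitless):\n")
  print(round(x$qc$pial_mean, 3))
  cat(sprintf("  %d pial voxels, %d negative-M, %d negative-G\n",
              x$qc$n_pial, x$qc$n_negative_M, x$qc$n_negative_G))
  invisible(x)
}

#' Full thickness measurement from nested labels
#'
#' Convenience wrapper: builds the three boundary levelsets (CSF/GM from
#' the cortex region, GM/mGM from the inner region, mGM/WM from the WM
#' region) and evaluates [thickness_at_pial()].
#'
#' @param labels A `nested_labels` object.
#' @return A `thickness_maps` object.
#' @export
cortical_thickness <- function(labels) {
  stopifnot(inherits(labels, "nested_labels"))
  sp <- labels$spacing; aff <- labels$affine
  phi_c <- signed_distance(region_cortex(labels), sp, aff, "csf_gm")
  phi_g <- signed_distance(region_inner(labels), sp, aff, "gm_mgm")
  phi_w <- signed_distance(region_wm(labels), sp, aff, "mgm_wm")
  thickness_at_pial(phi_c, phi_g, phi_w)
}

#' Sample a thickness metric on a surface voxel set
#'
#' Nearest-neighbour lookup of a metric volume at a set of surface voxels.
#' Voxels falling outside the defined (cortex) region are kept in the
#' output but flagged.
#'
#' @param maps A `thickness_maps` object.
#' @param metric One of `"T"`, `"G"`, `"M"`, `"P"`.
#' @param surface Logical 3D array, or an n x 3 matrix of voxel indices
#'   (1-based).
#' @return `data.frame` with columns `i`, `j`, `k`, `value`,
#'   `outside_cortex`. Empty surface sets yield an empty table.
#' @export
sample_metric_on_surface <- function(maps, metric = c("T", "G", "M", "P"),
                                     surface) {
  stopifnot(inherits(maps, "thickness_maps"))
  metric <- match.arg(metric)
  vol <- maps[[metric]]$data
  d <- dim(vol)
  if (is.matrix(surface)) {
    ijk <- surface
  } else {
    storage.mode(surface) <- "logical"
    ijk <- which(surface, arr.ind = TRUE)
  }
  if (nrow(ijk) == 0)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      value = numeric(), outside_cortex = logical()))
  if (any(ijk < 1) || any(ijk[, 1] > d[1]) || any(ijk[, 2] > d[2]) ||
      any(ijk[, 3] > d[3]))
    stop("surface voxel indices fall outside the grid")
  lin <- (ijk[, 3] - 1L) * d[1] * d[2] + (ijk[, 2] - 1L) * d[1] + ijk[, 1]
  vals <- vol[lin]
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3], value = vals,
             outside_cortex = is.na(vals))
}

#' Write thickness maps to NIfTI
#'
#' Writes `T`, `G`, `M`, `P` plus a validity mask. `NA` (non-cortex)
#' voxels become 0 on disk; the validity mask distinguishes true zeros.
#'
#' @param maps A `thickness_maps` object.
#' @param prefix Output path prefix; files are `<prefix>T.nii.gz` etc.
#' @param description Optional NIfTI `descrip` string.
#' @return Named character vector of paths, invisibly.
#' @export
write_thickness_maps <- function(maps, prefix, description = NULL) {
  stopifnot(inherits(maps, "thickness_maps"))
  paths <- c()
  for (met in c("T", "G", "M", "P")) {
    p <- paste0(prefix, met, ".nii.gz")
    write_volume(maps[[met]], p, na_fill = 0, description = description)
    paths[met] <- p
  }
  v <- maps$T
  valid <- vol3d(array(as.numeric(maps$cortex), dim(v$data)),
                 spacing = v$spacing, affine = v$affine, unit = "binary")
  paths["valid"] <- paste0(prefix, "valid.nii.gz")
  write_volume(valid, paths["valid"], description = description)
  invisible(paths)
}
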