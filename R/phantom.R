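#' Specify a synthetic laminar phantom
#'
#' Describes a cerebrum-masked ratio-image phantom with three nested
#' intensity classes (GM < mGM < WM), additive Gaussian noise and a smooth
#' multiplicative bias field, together with analytic ground-truth layer
#' thicknesses. Geometries:
#' \describe{
#'   \item{`spherical_shell`}{concentric spheres: WM core of radius
#'     `r_wm_inner`, mGM shell out to `r_gm_mgm`, GM shell out to the pial
#'     radius `r_pial`.}
#'   \item{`folded_shell`}{as above with a smooth sinusoidal radial offset
#'     added to *all* three radii, so the surfaces undulate while the radial
#'     layer thicknesses are preserved (thickness perpendicular to a tilted
#'     surface is slightly below the radial value, so truth is approximate
#'     at high fold amplitude).}
#'   \item{`slab`}{flat layers stacked along z: WM up to `r_wm_inner` mm
#'     from the lower grid face, mGM to `r_gm_mgm`, GM to `r_pial`.}
#' }
#' Defaults describe the reference validation phantom: a 64^3, 1 mm
#' isotropic spherical shell with radii 24/20/17 mm (truth T = 7, G = 4,
#' M = 3 mm), unit class contrast and noise sd of 5% of that contrast.
#'
#' @param geometry `"spherical_shell"`, `"folded_shell"` or `"slab"`.
#' @param r_pial,r_gm_mgm,r_wm_inner Boundary radii/heights in mm,
#'   strictly decreasing and positive.
#' @param intensities Class mean intensities `(c_GM, c_mGM, c_WM)`,
#'   strictly increasing (T1-weighted signal grows with myelin).
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param bias_amplitude Peak fractional deviation of the multiplicative
#'   bias field (a degree-2 polynomial in normalized coordinates), in
#'   `[0, 1)`.
#' @param spacing Voxel size in mm (length 1 or 3).
#' @param shape Grid size (length 1 or 3).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param fold_amp_mm,fold_freq Radial offset amplitude (mm) and angular
#'   frequency for `folded_shell`.
#' @param supersample If `TRUE`, simulate partial volume by rendering
#'   class intensities on a 3x supersampled grid and box-averaging.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("spherical_shell", "folded_shell",
                                      "slab"),
                         r_pial = 24, r_gm_mgm = 20, r_wm_inner = 17,
                         intensities = c(1, 2, 3), noise_sd = 0.05,
                         bias_amplitude = 0, spacing = 1, shape = 64,
                         seed = 1, fold_amp_mm = 1.5, fold_freq = 3,
                         supersample = FALSE) {
  geometry <- match.arg(geometry)
  spacing <- rep_len(as.numeric(spacing), 3L)
  shape <- rep_len(as.integer(shape), 3L)
  if (!(r_pial > r_gm_mgm && r_gm_mgm > r_wm_inner && r_wm_inner > 0))
    stop("radii must satisfy r_pial > r_gm_mgm > r_wm_inner > 0")
  if (!(length(intensities) == 3 && all(diff(intensities) > 0)))
    stop("intensities must be 3 strictly increasing values")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must lie in [0, 1)")
  ext <- shape * spacing
  if (geometry %in% c("spherical_shell", "folded_shell")) {
    margin <- r_pial + (if (geometry == "folded_shell") fold_amp_mm else 0)
    if (any(ext / 2 - margin < 2 * spacing))
      stop("shell does not fit inside the grid with a 2-voxel margin")
  } else {
    if (ext[3] - r_pial < 2 * spacing[3])
      stop("slab does not fit inside the grid with a 2-voxel margin")
  }
  thick <- c(G = r_pial - r_gm_mgm, M = r_gm_mgm - r_wm_inner)
  if (any(thick < max(spacing)))
    warning("layer thinner than one voxel: partial-volume stress test")
  structure(list(geometry = geometry, r_pial = r_pial, r_gm_mgm = r_gm_mgm,
                 r_wm_inner = r_wm_inner, intensities = intensities,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 spacing = spacing, shape = shape, seed = as.integer(seed),
                 fold_amp_mm = fold_amp_mm, fold_freq = fold_freq,
                 supersample = supersample),
            class = "phantom_spec")
}

# signed "depth coordinate": distance from the phantom centre (shells) or
# from the lower z face (slab), per voxel centre, optionally on a
# supersampled grid
phantom_depth <- function(spec, spacing, shape) {
  cx <- shape * spacing / 2
  xs <- (seq_len(shape[1]) - 0.5) * spacing[1]
  ys <- (seq_len(shape[2]) - 0.5) * spacing[2]
  zs <- (seq_len(shape[3]) - 0.5) * spacing[3]
  if (spec$geometry == "slab") {
    return(array(rep(zs, each = shape[1] * shape[2]), shape))
  }
  dx <- xs - cx[1]; dy <- ys - cx[2]; dz <- zs - cx[3]
  r <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  if (spec$geometry == "folded_shell") {
    # smooth angular offset added to every boundary radius
    theta <- atan2(array(rep(dy, each = shape[1]), shape),
                   array(dx, shape))
    zn <- array(rep(dz, each = shape[1] * shape[2]), shape) /
      pmax(r, .Machine$double.eps)
    offset <- spec$fold_amp_mm * sin(spec$fold_freq * theta) * (1 - zn^2)
    r <- r - offset
  }
  r
}

phantom_labels <- function(spec, spacing = spec$spacing, shape = spec$shape) {
  d <- phantom_depth(spec, spacing, shape)
  lab <- array(0L, shape)
  lab[d <= spec$r_pial] <- 1L
  lab[d <= spec$r_gm_mgm] <- 2L
  lab[d <= spec$r_wm_inner] <- 3L
  lab
}

# degree-2 polynomial multiplicative bias field in normalized coords,
# scaled so its peak fractional deviation equals `amp`
phantom_bias <- function(amp, shape, coef) {
  if (amp <= 0) return(array(1, shape))
  xs <- seq(-1, 1, length.out = shape[1])
  ys <- seq(-1, 1, length.out = shape[2])
  zs <- seq(-1, 1, length.out = shape[3])
  X <- array(xs, shape)
  Y <- array(rep(ys, each = shape[1]), shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), shape)
  f <- coef[1] * X + coef[2] * Y + coef[3] * Z +
    coef[4] * X^2 + coef[5] * Y^2 + coef[6] * Z^2 +
    coef[7] * X * Y + coef[8] * X * Z + coef[9] * Y * Z
  1 + amp * f / max(abs(f))
}

#' Generate a phantom ratio image with ground truth
#'
#' Renders the phantom described by `spec`: piecewise-constant class
#' intensities, multiplied by the smooth bias field, plus additive
#' Gaussian noise, restricted to the cerebrum mask (background 0). The
#' truth component carries the generating label volume, the mask and the
#' analytic thickness truth (`T = G + M`, `P = M/T`, exact).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `ratio` ([vol3d]), and `truth`: a list of
#'   `labels` ([vol3d]), `mask` (`mask_vol3d`), and scalars `T`, `G`,
#'   `M`, `P`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  coef <- stats::runif(9, -1, 1)
  if (spec$supersample) {
    f <- 3L
    lab_hi <- phantom_labels(spec, spacing = spec$spacing / f,
                             shape = spec$shape * f)
    img_hi <- array(0, dim(lab_hi))
    img_hi[lab_hi > 0] <- spec$intensities[lab_hi[lab_hi > 0]]
    img <- box_average3(img_hi, f)
    lab <- phantom_labels(spec)
  } else {
    lab <- phantom_labels(spec)
    img <- array(0, spec$shape)
    img[lab > 0] <- spec$intensities[lab[lab > 0]]
  }
  m <- lab > 0L
  bias <- phantom_bias(spec$bias_amplitude, spec$shape, coef)
  img <- img * bias
  if (spec$noise_sd > 0)
    img[m] <- img[m] + stats::rnorm(sum(m), 0, spec$noise_sd)
  img[!m] <- 0
  sp <- spec$spacing
  truth <- list(labels = vol3d(lab, spacing = sp, unit = "label"),
                mask = as_mask(array(as.numeric(m), spec$shape),
                               spacing = sp),
                T = spec$r_pial - spec$r_wm_inner,
                G = spec$r_pial - spec$r_gm_mgm,
                M = spec$r_gm_mgm - spec$r_wm_inner)
  truth$P <- truth$M / truth$T
  list(ratio = vol3d(img, spacing = sp, unit = "ratio"), truth = truth)
}

box_average3 <- function(a, f) {
  d <- dim(a) / f
  out <- array(0, d)
  for (di in 1:f) for (dj in 1:f) for (dk in 1:f)
    out <- out + a[seq(di, by = f, length.out = d[1]),
                   seq(dj, by = f, length.out = d[2]),
                   seq(dk, by = f, length.out = d[3])]
  out / f^3
}

#' Generate a paired T1w/PDw phantom
#'
#' Produces the raw inputs of the ratio-image preprocessor: a T1-weighted
#' volume (class intensities x bias + noise) and a proton-density-weighted
#' volume (constant tissue value x the *same* bias + noise), so dividing
#' by the median-filtered PDw cancels the bias up to noise and filter edge
#' effects.
#'
#' @param spec A [phantom_spec()].
#' @param pd_value Constant PDw tissue intensity (default 2).
#' @return List with `t1w`, `pdw` ([vol3d]) and `mask` (`mask_vol3d`),
#'   plus the generating `truth` as in [generate_phantom()].
#' @export
generate_paired_t1w_pdw <- function(spec, pd_value = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  coef <- stats::runif(9, -1, 1)
  lab <- phantom_labels(spec)
  m <- lab > 0L
  bias <- phantom_bias(spec$bias_amplitude, spec$shape, coef)
  t1w <- array(0, spec$shape)
  t1w[m] <- spec$intensities[lab[m]]
  t1w <- t1w * bias
  pdw <- array(pd_value, spec$shape) * bias
  if (spec$noise_sd > 0) {
    t1w[m] <- t1w[m] + stats::rnorm(sum(m), 0, spec$noise_sd)
    pdw <- pdw + array(stats::rnorm(length(pdw), 0, spec$noise_sd),
                       spec$shape)
  }
  t1w[!m] <- 0
  sp <- spec$spacing
  list(t1w = vol3d(t1w, spacing = sp, unit = "intensity"),
       pdw = vol3d(pdw, spacing = sp, unit = "intensity"),
       mask = as_mask(array(as.numeric(m), spec$shape), spacing = sp),
       truth = list(labels = vol3d(lab, spacing = sp, unit = "label"),
                    T = spec$r_pial - spec$r_wm_inner,
                    G = spec$r_pial - spec$r_gm_mgm,
                    M = spec$r_gm_mgm - spec$r_wm_inner))
}

#' Simulate a two-group phantom cohort
#'
#' Builds per-subject phantom specifications mirroring a case-control
#' imaging study: "control" subjects get between-subject multiplicative
#' jitter on the layer thicknesses (and WM core radius), "case" subjects
#' additionally have their unmyelinated (G) and/or myelinated (M) layer
#' thickness scaled by `(1 - effect)`. All subjects share the grid, so
#' their metric maps are directly averageable.
#'
#' @param template A [phantom_spec()] giving the group-mean geometry.
#' @param n_per_group Subjects per group (>= 2).
#' @param effect Named fractional decreases, e.g. `c(G = 0, M = 0.15)`;
#'   absolute values below 1.
#' @param jitter_sd Between-subject sd of the multiplicative jitter
#'   (default 0.02).
#' @param seed Integer seed.
#' @return List with `subjects` (list of per-subject lists: `id`,
#'   `group`, `spec`) and `truth` (data.frame of per-subject true
#'   T/G/M/P).
#' @export
make_cohort <- function(template, n_per_group = 10,
                        effect = c(G = 0, M = 0), jitter_sd = 0.02,
                        seed = 1) {
  stopifnot(inherits(template, "phantom_spec"))
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  eff <- c(G = 0, M = 0)
  eff[names(effect)] <- effect
  if (any(abs(eff) >= 1)) stop("effect magnitudes must be < 1")
  set.seed(seed)
  g0 <- template$r_pial - template$r_gm_mgm
  m0 <- template$r_gm_mgm - template$r_wm_inner
  w0 <- template$r_wm_inner
  subjects <- list()
  rows <- list()
  n_total <- 2L * n_per_group
  groups <- rep(c("control", "case"), each = n_per_group)
  for (s in seq_len(n_total)) {
    jit <- stats::rnorm(3, 1, jitter_sd)
    g_s <- g0 * jit[1]
    m_s <- m0 * jit[2]
    w_s <- w0 * jit[3]
    if (groups[s] == "case") {
      g_s <- g_s * (1 - eff["G"])
      m_s <- m_s * (1 - eff["M"])
    }
    if (min(g_s, m_s) < max(template$spacing))
      warning("subject ", s, ": layer thinner than one voxel")
    sp_s <- template
    sp_s$r_wm_inner <- w_s
    sp_s$r_gm_mgm <- w_s + m_s
    sp_s$r_pial <- w_s + m_s + g_s
    sp_s$seed <- template$seed + 1000L + s
    id <- sprintf("%s%02d", substr(groups[s], 1, 4), s)
    subjects[[s]] <- list(id = id, group = groups[s], spec = sp_s)
    rows[[s]] <- data.frame(subject = id, group = groups[s],
                            T = g_s + m_s, G = g_s, M = m_s,
                            P = m_s / (g_s + m_s))
  }
  list(subjects = subjects, truth = do.call(rbind, rows))
}
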