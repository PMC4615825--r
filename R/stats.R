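#' Summarize thickness metrics over a region of interest
#'
#' Means and standard deviations of T, G, M, P over the voxels where the
#' ROI mask intersects the defined (cortex) region of the maps; undefined
#' voxels inside the ROI are excluded and counted.
#'
#' @param maps A `thickness_maps` object.
#' @param roi ROI mask (`mask_vol3d` or logical array) on the same grid.
#' @param subject,group,roi_name Identifiers copied into the output row.
#' @return One-row `data.frame` with `subject`, `group`, `roi`,
#'   `n_voxels`, `n_undefined`, and `mean_`/`sd_` columns for T, G, M, P.
#' @export
roi_extract <- function(maps, roi, subject = "subj", group = NA_character_,
                        roi_name = "roi") {
  stopifnot(inherits(maps, "thickness_maps"))
  if (inherits(roi, "mask_vol3d")) {
    stop_if_incompatible(maps$T, roi, what = "maps/roi")
    roi <- mask_logical(roi)
  }
  if (!identical(dim(roi), dim(maps$T$data)))
    stop("ROI grid does not match the thickness maps")
  sel <- roi & !is.na(maps$T$data)
  n_undef <- sum(roi) - sum(sel)
  if (!any(sel))
    stop("ROI does not intersect the defined (cortex) region")
  out <- data.frame(subject = subject, group = group, roi = roi_name,
                    n_voxels = sum(sel), n_undefined = n_undef)
  for (met in c("T", "G", "M", "P")) {
    v <- maps[[met]]$data[sel]
    out[[paste0("mean_", met)]] <- mean(v)
    out[[paste0("sd_", met)]] <- stats::sd(v)
  }
  out
}

#' Voxelwise average atlas of co-registered metric maps
#'
#' Averages thickness maps from multiple subjects voxel by voxel,
#' restricted to voxels defined in at least `min_coverage` of subjects
#' (default 50%); elsewhere the atlas is `NA`. Inputs must already live
#' on a shared grid (registration is upstream of this package).
#'
#' @param maps_list List (length >= 2) of `thickness_maps` on one grid.
#' @param min_coverage Minimum fraction of subjects with a defined value.
#' @return List with `atlas` (a `thickness_maps`-like list of [vol3d]
#'   T/G/M/P), and `coverage` (a [vol3d] of per-voxel subject counts).
#' @export
average_atlas <- function(maps_list, min_coverage = 0.5) {
  if (length(maps_list) < 2) stop("need at least 2 subjects to average")
  ref <- maps_list[[1]]$T
  for (m in maps_list[-1]) stop_if_incompatible(ref, m$T, what = "atlas inputs")
  n <- length(maps_list)
  defined <- Reduce(`+`, lapply(maps_list, function(m) !is.na(m$T$data)))
  atlas <- list()
  for (met in c("T", "G", "M", "P")) {
    s <- array(0, dim(ref$data))
    cnt <- array(0L, dim(ref$data))
    for (m in maps_list) {
      a <- m[[met]]$data
      ok <- !is.na(a)
      a[!ok] <- 0
      s <- s + a
      cnt <- cnt + ok
    }
    avg <- s / pmax(cnt, 1L)
    avg[cnt < min_coverage * n] <- NA
    atlas[[met]] <- vol3d(avg, spacing = ref$spacing, affine = ref$affine,
                          unit = maps_list[[1]][[met]]$unit)
  }
  list(atlas = atlas,
       coverage = vol3d(array(as.numeric(defined), dim(ref$data)),
                        spacing = ref$spacing, affine = ref$affine,
                        unit = "count"))
}

# resolve a metric name to a summary column: prefers the ROI-summary
# `mean_<metric>` column, falls back to a bare column of that name (as in
# cohort truth tables)
metric_column <- function(df, metric) {
  cand <- c(paste0("mean_", metric), metric)
  hit <- cand[cand %in% names(df)]
  if (!length(hit))
    stop("no column `", cand[1], "` or `", metric, "` in summaries")
  hit[1]
}

#' Compare a thickness metric between groups
#'
#' One-way ANOVA across groups with Tukey HSD pairwise comparisons,
#' preceded by the assumption checks used in ROI thickness studies:
#' Anderson-Darling normality per group and Levene's test of variance
#' homogeneity. Assumption violations are reported (and warned about) but
#' do not abort the comparison. For two groups the ANOVA F-test is
#' equivalent to the two-sample t-test; the equivalent t statistic is
#' exposed in the output.
#'
#' @param summaries `data.frame` of ROI summaries ([roi_extract()] rows)
#'   with a `group` column; >= 2 groups, >= 3 subjects per group.
#' @param metric One of `"T"`, `"G"`, `"M"`, `"P"` (uses the
#'   `mean_<metric>` column), or the name of any numeric column.
#' @param alpha Significance level for the Tukey comparisons.
#' @return Object of class `group_comparison`: group means/sds,
#'   normality p-values, Levene p, ANOVA F and p, equivalent |t| (two
#'   groups), Tukey table with adjusted p-values and significance at
#'   `alpha`, and the case-vs-control percent difference when groups are
#'   named `control`/`case`.
#' @export
group_compare <- function(summaries, metric = "M", alpha = 0.05) {
  col <- metric_column(summaries, metric)
  vals <- summaries[[col]]
  grp <- factor(summaries$group)
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  if (any(table(grp) < 3)) stop("need at least 3 subjects per group")
  if (any(tapply(vals, grp, stats::sd) == 0))
    stop("a group has zero variance; comparison undefined")

  norm_p <- vapply(levels(grp), function(g) {
    v <- vals[grp == g]
    if (length(v) < 8) {
      # AD test needs n >= 8; fall back to Shapiro-Wilk for tiny groups
      stats::shapiro.test(v)$p.value
    } else {
      nortest::ad.test(v)$p.value
    }
  }, numeric(1))
  lev <- car::leveneTest(vals ~ grp)
  lev_p <- lev[["Pr(>F)"]][1]
  if (any(norm_p < alpha))
    warning("Anderson-Darling normality check failed in group(s): ",
            paste(names(norm_p)[norm_p < alpha], collapse = ", "),
            "; proceeding with ANOVA regardless")
  if (lev_p < alpha)
    warning("Levene test indicates unequal variances (p = ",
            signif(lev_p, 3), "); proceeding with ANOVA regardless")

  fit <- stats::aov(vals ~ grp)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  tukey <- data.frame(comparison = rownames(tuk), diff = tuk[, "diff"],
                      lwr = tuk[, "lwr"], upr = tuk[, "upr"],
                      p_adj = tuk[, "p adj"],
                      significant = tuk[, "p adj"] < alpha,
                      row.names = NULL)

  gm <- tapply(vals, grp, mean)
  gs <- tapply(vals, grp, stats::sd)
  gn <- as.vector(table(grp))
  pct_diff <- if (all(c("control", "case") %in% levels(grp)))
    100 * (gm[["case"]] - gm[["control"]]) / gm[["control"]] else NA_real_

  structure(list(metric = metric, alpha = alpha,
                 groups = data.frame(group = levels(grp), n = gn,
                                     mean = as.vector(gm),
                                     sd = as.vector(gs)),
                 normality_p = norm_p, levene_p = lev_p,
                 equal_variance = lev_p >= alpha,
                 anova_F = f_stat, anova_p = p_val,
                 t_equivalent = if (nlevels(grp) == 2) sqrt(f_stat) else NA_real_,
                 tukey = tukey, percent_difference = pct_diff),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> metric %s: F = %.3f, p = %.4g\n",
              x$metric, x$anova_F, x$anova_p))
  print(x$groups, row.names = FALSE)
  if (!is.na(x$percent_difference))
    cat(sprintf("  case vs control: %+.2f%%\n", x$percent_difference))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Minimal detectable effect from control-group variance
#'
#' The smallest percent difference in group means that a two-sided
#' two-sample t-test would detect at the stated significance level and
#' power, given the control group's standard deviation and `n` subjects
#' per group (noncentral-t solution via [stats::power.t.test()]),
#' expressed as percent of the control mean.
#'
#' @param control_summaries ROI summary rows for the control group.
#' @param metric Metric name as in [group_compare()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param n Subjects per group; defaults to the number of control rows.
#' @return List with `percent` (minimal detectable percent difference),
#'   `delta` (absolute difference, metric units), `control_mean`,
#'   `control_sd`, `n`, `alpha`, `power`.
#' @export
detectable_effect <- function(control_summaries, metric = "M",
                              alpha = 0.05, power = 0.8, n = NULL) {
  col <- metric_column(control_summaries, metric)
  vals <- control_summaries[[col]]
  if (is.null(n)) n <- length(vals)
  if (n < 2) stop("need n >= 2 per group")
  s <- stats::sd(vals)
  mu <- mean(vals)
  if (!is.finite(s) || s <= 0) stop("degenerate control sd")
  pt <- stats::power.t.test(n = n, sd = s, sig.level = alpha, power = power,
                            type = "two.sample",
                            alternative = "two.sided", tol = 1e-9)
  list(percent = 100 * pt$delta / mu, delta = pt$delta,
       control_mean = mu, control_sd = s, n = n, alpha = alpha,
       power = power)
}
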