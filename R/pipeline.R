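#' Pipeline configuration
#'
#' Collects every tunable parameter of the thickness pipeline with the
#' method's reference defaults: 5 mm PDw median filter kernel, fuzziness
#' 2, spatial regularization off, membership thresholds 0.1 (WM) / 0.5
#' (mGM) / 0.5 (GM), 2 mm boundary smoothing kernel, alpha 0.05 and power
#' 0.8 for the ROI statistics. The configuration is a plain serializable
#' list; [run_pipeline()] writes the effective configuration beside its
#' outputs.
#'
#' @param kernel_mm PDw median filter kernel (mm).
#' @param fuzziness,beta,tol,max_iter FCM parameters, see [fcm_segment()].
#' @param wm_threshold,mgm_threshold,gm_threshold Membership thresholds,
#'   see [build_nested_labels()].
#' @param smooth_mm GM/mGM boundary smoothing kernel (mm).
#' @param alpha,power ROI statistics parameters.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(kernel_mm = 5, fuzziness = 2, beta = 0,
                            tol = 1e-8, max_iter = 200,
                            wm_threshold = 0.1, mgm_threshold = 0.5,
                            gm_threshold = 0.5, smooth_mm = 2,
                            alpha = 0.05, power = 0.8, seed = 1) {
  structure(list(kernel_mm = kernel_mm, fuzziness = fuzziness, beta = beta,
                 tol = tol, max_iter = max_iter,
                 wm_threshold = wm_threshold,
                 mgm_threshold = mgm_threshold,
                 gm_threshold = gm_threshold, smooth_mm = smooth_mm,
                 alpha = alpha, power = power, seed = as.integer(seed)),
            class = "pipeline_config")
}

# content hash of a stage: parameters + md5 of the input files
stage_hash <- function(params, files = character()) {
  files <- files[file.exists(files)]
  fh <- if (length(files)) unname(tools::md5sum(files)) else character()
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(deparse(params), fh), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full thickness pipeline
#'
#' Orchestrates phantom generation (when no scan inputs are given),
#' ratio-image preprocessing, three-class segmentation with nested-label
#' cleanup, levelset thickness measurement and (optionally) ROI
#' statistics, writing every artifact under `out_dir` together with a
#' manifest and the effective configuration. Completed stages are skipped
#' on re-runs when their parameter/input content hash is unchanged
#' (`force = TRUE` reruns everything). Each output NIfTI carries the run
#' id in its `descrip` header field.
#'
#' @param config A [pipeline_config()].
#' @param inputs Named list. Either `t1w`, `pdw`, `mask` file paths (the
#'   preprocess stage builds the ratio image), or `ratio` (a
#'   cerebrum-masked ratio NIfTI), or `NULL` to generate the default
#'   spherical phantom. Optional `roi`: ROI mask path for statistics.
#' @param out_dir Output directory (created if missing).
#' @param phantom A [phantom_spec()] used when `inputs` is `NULL`.
#' @param force Rerun all stages even if hashes match.
#' @param verbose Log stage progress.
#' @return The manifest (named list of artifact paths and stage
#'   metadata), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         out_dir = "mcthick_out", phantom = NULL,
                         force = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force)
    jsonlite::read_json(manifest_path) else list()
  run_id <- sprintf("mcthick-%08x", config$seed)
  say <- function(...) if (verbose) message("[", run_id, "] ", ...)
  t0 <- Sys.time()

  done <- function(stage, hash) {
    !force && !is.null(manifest[[stage]]) &&
      identical(manifest[[stage]]$hash, hash) &&
      all(file.exists(unlist(manifest[[stage]]$outputs)))
  }
  record <- function(stage, hash, outputs, extra = list()) {
    manifest[[stage]] <<- c(list(hash = hash, outputs = as.list(outputs),
                                 params = NULL), extra)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  ratio_path <- file.path(out_dir, "ratio.nii.gz")

  if (is.null(inputs) || (is.null(inputs$ratio) && is.null(inputs$t1w))) {
    if (is.null(phantom)) phantom <- phantom_spec(seed = config$seed)
    h <- stage_hash(list(stage = "phantom", spec = unclass(phantom)))
    if (done("phantom", h)) {
      say("phantom: up to date, skipping")
    } else {
      say("phantom: generating ", phantom$geometry, " phantom")
      ph <- generate_phantom(phantom)
      write_volume(ph$ratio, ratio_path, description = run_id)
      write_volume(ph$truth$labels, file.path(out_dir, "truth_labels.nii.gz"),
                   datatype = "int16", description = run_id)
      write_volume(ph$truth$mask, file.path(out_dir, "mask.nii.gz"),
                   datatype = "uint8", description = run_id)
      jsonlite::write_json(unclass(phantom),
                           file.path(out_dir, "phantom_spec.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      record("phantom", h, c(ratio_path,
                             file.path(out_dir, "truth_labels.nii.gz"),
                             file.path(out_dir, "mask.nii.gz")))
    }
    mask_path <- file.path(out_dir, "mask.nii.gz")
  } else if (!is.null(inputs$t1w)) {
    h <- stage_hash(list(stage = "preprocess", kernel = config$kernel_mm),
                    c(inputs$t1w, inputs$pdw, inputs$mask))
    mask_path <- inputs$mask
    if (done("preprocess", h)) {
      say("preprocess: up to date, skipping")
    } else {
      say("preprocess: ratio image (", config$kernel_mm, " mm median kernel)")
      t1w <- read_volume(inputs$t1w)
      pdw <- read_volume(inputs$pdw)
      mask <- read_mask(inputs$mask)
      ratio <- compute_ratio_image(t1w, pdw, mask,
                                   kernel_mm = config$kernel_mm)
      write_volume(ratio, ratio_path, description = run_id)
      record("preprocess", h, ratio_path)
    }
  } else {
    ratio_path <- inputs$ratio
    mask_path <- inputs$mask
  }

  seg_params <- config[c("fuzziness", "beta", "tol", "max_iter",
                         "wm_threshold", "mgm_threshold", "gm_threshold",
                         "smooth_mm")]
  h_seg <- stage_hash(c(list(stage = "segment"), seg_params), ratio_path)
  labels_path <- file.path(out_dir, "labels.nii.gz")
  if (done("segment", h_seg)) {
    say("segment: up to date, skipping")
  } else {
    say("segment: 3-class FCM (q=", config$fuzziness, ", beta=", config$beta,
        "), thresholds ", config$wm_threshold, "/", config$mgm_threshold,
        "/", config$gm_threshold)
    ratio <- read_volume(ratio_path, unit = "ratio")
    mask <- if (!is.null(mask_path) && file.exists(mask_path))
      read_mask(mask_path) else NULL
    mem <- fcm_segment(ratio, mask, fuzziness = config$fuzziness,
                       beta = config$beta, tol = config$tol,
                       max_iter = config$max_iter, seed = config$seed)
    labels <- build_nested_labels(mem, config$wm_threshold,
                                  config$mgm_threshold, config$gm_threshold)
    labels <- keep_largest_component(labels)
    labels <- smooth_inner_boundary(labels, config$smooth_mm)
    labels <- strip_pial_voxels(labels)
    write_volume(labels$labels, labels_path, datatype = "int16",
                 description = run_id)
    for (cls in names(mem$u))
      write_volume(mem$u[[cls]], file.path(out_dir,
                                           paste0("membership_", cls, ".nii.gz")),
                   na_fill = 0, description = run_id)
    jsonlite::write_json(list(centroids = mem$centroids,
                              iterations = mem$iterations,
                              converged = mem$converged,
                              objective = mem$objective),
                         file.path(out_dir, "segmentation_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("segment", h_seg, labels_path,
           list(centroids = mem$centroids))
  }

  h_thk <- stage_hash(list(stage = "thickness"), labels_path)
  thk_prefix <- file.path(out_dir, "thickness_")
  thk_paths <- paste0(thk_prefix, c("T", "G", "M", "P"), ".nii.gz")
  qc_path <- file.path(out_dir, "thickness_qc.json")
  if (done("thickness", h_thk)) {
    say("thickness: up to date, skipping")
  } else {
    say("thickness: levelset distances and T/G/M/P maps")
    lab_vol <- read_volume(labels_path, unit = "label")
    labels <- new_nested_labels(array(as.integer(round(lab_vol$data)),
                                      dim(lab_vol$data)),
                                lab_vol$spacing, lab_vol$affine)
    maps <- cortical_thickness(labels)
    write_thickness_maps(maps, thk_prefix, description = run_id)
    qc_json <- maps$qc
    qc_json$pial_mean <- as.list(qc_json$pial_mean)
    qc_json$pial_sd <- as.list(qc_json$pial_sd)
    jsonlite::write_json(qc_json, qc_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    record("thickness", h_thk, c(thk_paths, qc_path))
  }

  if (!is.null(inputs$roi)) {
    h_roi <- stage_hash(list(stage = "roi_stats", alpha = config$alpha),
                        c(labels_path, inputs$roi))
    roi_path <- file.path(out_dir, "roi_summary.csv")
    if (done("roi_stats", h_roi)) {
      say("roi-stats: up to date, skipping")
    } else {
      say("roi-stats: summarizing metrics over ROI")
      lab_vol <- read_volume(labels_path, unit = "label")
      labels <- new_nested_labels(array(as.integer(round(lab_vol$data)),
                                        dim(lab_vol$data)),
                                  lab_vol$spacing, lab_vol$affine)
      maps <- cortical_thickness(labels)
      roi <- read_mask(inputs$roi)
      summ <- roi_extract(maps, roi)
      utils::write.csv(summ, roi_path, row.names = FALSE)
      record("roi_stats", h_roi, roi_path)
    }
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(list(run_id = run_id), unclass(config)), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("pipeline finished in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}
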