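#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage default plus input/output locations and the global
#' seed. Unknown keys are rejected so a typo in a config cannot silently
#' fall back to a default.
#'
#' @param input Input directory of per-timepoint TIFFs, or a
#'   [timeseries()] passed directly.
#' @param output Output (run) directory.
#' @param pixel_size_um,z_step_um,bit_depth Voxel geometry of the input.
#' @param median_window Median filter window (NULL: from geometry).
#' @param upsample,search_radius,z_correct Registration settings.
#' @param detections Optional data.frame `(row, col)` of spine centers at
#'   the first time point, standing in for (or merged with) automatic
#'   detection.
#' @param classifier Optional trained classifier for automatic detection.
#' @param patch_um,nms_radius_um,confidence Detection settings.
#' @param roi_half_px,h_frac,refine_f,mock_radius_um Segmentation settings
#'   (`h_frac` is the h-maxima prominence as a fraction of ROI range).
#' @param neck_n,erosion_radius Neck-path settings.
#' @param fwhm_orientation_deg Optional named/numeric vector of per-spine
#'   profile orientations; FWHM volumes are computed only when provided.
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, output = tempfile("spinetrack_run_"),
                       pixel_size_um = 0.072, z_step_um = NULL,
                       bit_depth = 12L, median_window = NULL,
                       upsample = 100L, search_radius = 10L,
                       z_correct = TRUE, detections = NULL,
                       classifier = NULL, patch_um = 3.4,
                       nms_radius_um = 0.5, confidence = 0.5,
                       roi_half_px = 30L, h_frac = 0.1, refine_f = 0.5,
                       mock_radius_um = 0.6, neck_n = 8L,
                       erosion_radius = 1L, fwhm_orientation_deg = NULL,
                       seed = 1L) {
  cfg <- list(input = input, output = output,
              pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              bit_depth = as.integer(bit_depth),
              median_window = median_window, upsample = as.integer(upsample),
              search_radius = as.integer(search_radius),
              z_correct = z_correct, detections = detections,
              classifier = classifier, patch_um = patch_um,
              nms_radius_um = nms_radius_um, confidence = confidence,
              roi_half_px = as.integer(roi_half_px), h_frac = h_frac,
              refine_f = refine_f, mock_radius_um = mock_radius_um,
              neck_n = as.integer(neck_n),
              erosion_radius = as.integer(erosion_radius),
              fwhm_orientation_deg = fwhm_orientation_deg,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Run the full longitudinal spine analysis
#'
#' Load, chained global registration, MIP + median filtering, spine
#' detection at the first time point (automatic, manual, or merged),
#' dendrite segmentation per time point, then per spine and time point:
#' NMI local re-centering, head segmentation, neck-path extraction and IFI
#' (plus FWHM when an orientation is configured). Per-spine errors degrade
#' to flags so a longitudinal run always completes; results are written as
#' CSV/JSON plus mask TIFFs and are reproducible from (input, config,
#' seed) alone.
#'
#' @param config A [run_config()].
#' @return The run directory (invisibly); see `measurements.csv`,
#'   `shifts.csv`, `detections.csv`, `manifest.json` and `masks/` inside.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  geom <- voxel_geometry(config$pixel_size_um, config$pixel_size_um,
                         config$z_step_um, config$bit_depth)
  series <- if (inherits(config$input, "spine_timeseries")) config$input
  else load_timeseries(config$input, geom)
  geom <- series$stacks[[1]]$geometry
  reg <- register_timeseries(series, config$upsample, config$z_correct)
  series <- reg$series
  utils::write.csv(reg$shifts, file.path(config$output, "shifts.csv"),
                   row.names = FALSE)
  mw <- config$median_window %||% default_median_window(geom)
  mips <- lapply(series$stacks, function(s)
    median_filter2d(max_intensity_projection(s), mw))
  # detection at t = 1
  dets <- config$detections
  if (!is.null(config$classifier)) {
    auto <- detect_spines(mips[[1]], config$classifier,
                          nms_radius_um = config$nms_radius_um,
                          patch_um = config$patch_um,
                          confidence = config$confidence)
    dets <- if (is.null(dets)) auto[, c("row", "col")] else
      rbind(dets[, c("row", "col")], auto[, c("row", "col")])
  }
  if (is.null(dets) || nrow(dets) == 0L)
    stop("no spine detections: provide a classifier or manual detections")
  dets <- unique(round(dets[, c("row", "col")]))
  utils::write.csv(cbind(spine_id = seq_len(nrow(dets)), dets),
                   file.path(config$output, "detections.csv"),
                   row.names = FALSE)
  # dendrite per time point
  dend <- lapply(mips, function(m)
    tryCatch(segment_dendrite(m, median_window = 1L),
             error = function(e) NULL))
  dir.create(file.path(config$output, "masks"), showWarnings = FALSE)
  rows <- list()
  for (sp in seq_len(nrow(dets))) {
    masks <- tryCatch(
      segment_spine_timeseries(series, as.numeric(dets[sp, ]),
                               half_size = config$roi_half_px,
                               search_radius = config$search_radius,
                               f = config$refine_f,
                               mock_radius_um = config$mock_radius_um),
      error = function(e) NULL)
    for (t in seq_along(series$stacks)) {
      flags <- character(0)
      area <- NA_integer_
      ifi_raw <- NA_real_
      ifi_norm <- NA_real_
      neck_um <- NA_real_
      fwhm_v <- NA_real_
      prov <- "failed"
      if (!is.null(masks)) {
        hm <- masks[[t]]
        prov <- hm$provenance
        if (prov == "missing" || !any(hm$mask)) {
          flags <- c(flags, "missing")
        } else {
          area <- hm$area_px
          dd <- dend[[t]]
          if (!is.null(dd) && dd$median_intensity > 0) {
            win <- roi_window(hm$seed, config$roi_half_px, t)
            roi <- crop_roi(mips[[t]], win)
            m <- ifi_volume(mips[[t]]$data, hm$mask, fov_min = min(roi),
                            dendrite_median = dd$median_intensity)
            ifi_raw <- m$raw_sum
            ifi_norm <- m$normalized_volume
            if (m$clamped) flags <- c(flags, "ifi-clamped")
            np <- tryCatch(
              suppressWarnings(
                extract_neck_path(series$stacks[[t]], c(hm$seed, 1L),
                                  dd$mask, head_mask = hm$mask,
                                  n = config$neck_n,
                                  erosion_radius = config$erosion_radius)),
              error = function(e) NULL)
            if (!is.null(np)) {
              neck_um <- np$length_um
              flags <- c(flags, np$flags)
              if (!np$trimmed) flags <- c(flags, "untrimmed")
            } else flags <- c(flags, "neck-failed")
          } else flags <- c(flags, "no-dendrite")
          ori <- orientation_for(config$fwhm_orientation_deg, sp)
          if (!is.na(ori)) {
            fw <- tryCatch(
              fwhm_volume(mips[[t]], hm$seed, ori),
              error = function(e) NULL)
            if (!is.null(fw)) fwhm_v <- fw$volume_um3
            else flags <- c(flags, "fwhm-failed")
          }
          if (prov == "mock-boundary") flags <- c(flags, "mock")
        }
      } else flags <- "segmentation-failed"
      rows[[length(rows) + 1L]] <- data.frame(
        spine_id = sp, t = t, area_px = area, ifi_raw = ifi_raw,
        ifi_normalized = ifi_norm, fwhm_volume_um3 = fwhm_v,
        neck_length_um = neck_um, provenance = prov,
        flags = paste(flags, collapse = ";"))
    }
    if (!is.null(masks)) {
      lab <- Reduce(`+`, lapply(seq_along(masks), function(t)
        masks[[t]]$mask * t))
      save_zstack(array(unlist(lapply(masks, function(m) m$mask * 1)),
                        c(dim(masks[[1]]$mask), length(masks))),
                  file.path(config$output, "masks",
                            sprintf("spine_%03d.tif", sp)))
    }
  }
  meas <- do.call(rbind, rows)
  write_measurements(meas, file.path(config$output, "measurements.csv"))
  manifest <- config
  manifest$input <- if (is.character(config$input)) config$input else
    "<in-memory timeseries>"
  manifest$classifier <- if (is.null(config$classifier)) NULL else
    "<trained classifier>"
  manifest$detections <- NULL
  class(manifest) <- NULL
  jsonlite::write_json(
    list(config = manifest, n_spines = nrow(dets),
         n_timepoints = length(series$stacks),
         package_version = as.character(utils::packageVersion("spinetrack"))),
    file.path(config$output, "manifest.json"), auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(config$output)
}

orientation_for <- function(ori, sp) {
  if (is.null(ori)) return(NA_real_)
  if (length(ori) == 1L && is.null(names(ori))) return(as.numeric(ori))
  nm <- as.character(sp)
  if (!is.null(names(ori)) && nm %in% names(ori))
    return(as.numeric(ori[[nm]]))
  if (sp <= length(ori)) return(as.numeric(ori[[sp]]))
  NA_real_
}

# missing values stay empty cells, never zeros
write_measurements <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Merge manual corrections into a completed run
#'
#' Manual spine centers are added to the detections, manual masks override
#' the automatic head mask of one spine/time point, and manual base points
#' override neck candidates; only affected spines are recomputed.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param config The [run_config()] used for the run.
#' @param manual_centers Optional data.frame `(row, col)` of extra spines.
#' @param manual_masks Optional named list `spine_id:t` -> logical matrix.
#' @param manual_bases Optional data.frame `(spine_id, t, row, col)` of
#'   neck base points.
#' @return The run directory (invisibly).
#' @export
merge_manual_inputs <- function(run_dir, config, manual_centers = NULL,
                                manual_masks = NULL, manual_bases = NULL) {
  if (is.null(manual_centers) && is.null(manual_masks) &&
      is.null(manual_bases))
    return(invisible(run_dir))
  if (!is.null(manual_centers)) {
    if (!all(c("row", "col") %in% names(manual_centers)))
      stop("manual centers must have columns row, col")
    config$detections <- rbind(
      if (is.null(config$detections)) NULL else
        config$detections[, c("row", "col")],
      manual_centers[, c("row", "col")])
  }
  config$manual_masks <- manual_masks
  config$manual_bases <- manual_bases
  run_pipeline(config)
}

#' Export spine records to CSV/JSON
#'
#' Writes the per-spine time series table, a JSON manifest of the
#' configuration that produced it, and (optionally) labelled mask TIFFs.
#'
#' @param records data.frame as produced by [run_pipeline()]
#'   (`measurements.csv` schema).
#' @param out_dir Output directory.
#' @param config Optional [run_config()] recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
export_results <- function(records, out_dir, config = NULL) {
  stopifnot(nrow(records) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_measurements(records, file.path(out_dir, "measurements.csv"))
  manifest <- list(created = "spinetrack export",
                   n_rows = nrow(records))
  if (!is.null(config)) {
    cfg <- config
    cfg$classifier <- NULL
    cfg$input <- if (is.character(cfg$input)) cfg$input else NULL
    class(cfg) <- NULL
    manifest$config <- cfg
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
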