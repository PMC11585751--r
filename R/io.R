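#' Read an RGB brightfield image
#'
#' Reads a PNG or TIFF file into an [rgb_image()]. Greyscale images are
#' expanded to three channels and any alpha plane is dropped. The
#' physical resolution must be supplied by the caller; no metadata
#' sniffing is attempted.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param mpp microns per pixel.
#' @return An [rgb_image()].
#' @export
read_image_rgb <- function(path, mpp) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext)))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  rgb_image(round(arr * 255), mpp = mpp)
}

#' Write an RGB image as PNG or TIFF
#'
#' @param image an [rgb_image()].
#' @param path destination path; the extension selects the format.
#' @return Invisibly, `path`.
#' @export
write_image_rgb <- function(image, path) {
  if (!inherits(image, "rgb_image")) stop("`image` must be an rgb_image")
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext)))
  invisible(path)
}

#' Read ROI polygons from a GeoJSON FeatureCollection
#'
#' Parses `Polygon` features into [roi_polygon()] objects; coordinates
#' are interpreted in pixel space (x along columns, y along rows, origin
#' at the image's top-left corner). Non-polygon features are skipped
#' with a warning. The feature `id` (or `properties$id` / `$name`, else
#' a running index) becomes the ROI id.
#'
#' @param path GeoJSON file path.
#' @return List of [roi_polygon()] objects.
#' @export
read_roi_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("expected a GeoJSON Feature or FeatureCollection")
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      warning(sprintf("feature %d has geometry '%s'; only Polygon is supported, skipping",
                      i, if (is.null(geom)) "none" else geom$type))
      next
    }
    ring <- geom$coordinates[[1]] # exterior ring
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    id <- f$id %||% f$properties$id %||% f$properties$name %||%
      sprintf("roi%d", i)
    out[[length(out) + 1L]] <- roi_polygon(v, id = id)
  }
  if (length(out) == 0)
    stop("annotation file contains no usable Polygon feature")
  out
}

#' Write ROI polygons as a GeoJSON FeatureCollection
#'
#' @param rois list of [roi_polygon()] objects.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_roi_annotations <- function(rois, path) {
  feats <- lapply(rois, function(p) {
    v <- p$vertices
    ring <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
    ring[[length(ring) + 1L]] <- ring[[1L]] # close the ring
    list(type = "Feature", id = p$id,
         properties = list(id = p$id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default run configuration
#'
#' The full parameter tree for a scoring run, with the package defaults:
#' stain vectors, segmentation parameters, positivity threshold, image
#' resolution and RNG seed. A YAML config file ([read_run_config()]) may
#' override any subset; unknown keys are rejected.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    mpp = 0.5,
    seed = 1L,
    stains = list(hematoxylin = c(0.650, 0.704, 0.286),
                  dab = c(0.269, 0.568, 0.778)),
    segmentation = list(threshold_method = "otsu",
                        fixed_threshold = NA,
                        min_distance_px = 7,
                        min_height = 0.2,
                        min_area_um2 = 10,
                        max_area_um2 = 400,
                        connectivity = 8),
    classification = list(dab_threshold = 0.15,
                          statistic = "mean")
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()]. Any key
#' not present in the default tree is an error, so typos fail loudly
#' instead of silently running with defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_validate <- function(def, usr, prefix) {
    for (nm in names(usr)) {
      if (!nm %in% names(def))
        stop(sprintf("unknown config key '%s%s'", prefix, nm))
      if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        def[[nm]] <- merge_validate(def[[nm]], usr[[nm]],
                                    paste0(prefix, nm, "."))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  out <- merge_validate(unclass(cfg), user, "")
  if (out$mpp <= 0) stop("config: mpp must be positive")
  if (out$classification$dab_threshold < 0)
    stop("config: dab_threshold must be >= 0")
  structure(out, class = "run_config")
}

config_seg_params <- function(config) {
  s <- config$segmentation
  seg_params(threshold_method = s$threshold_method,
             fixed_threshold = if (is.na(s$fixed_threshold)) NULL
                               else s$fixed_threshold,
             min_distance_px = s$min_distance_px,
             min_height = s$min_height,
             min_area_um2 = s$min_area_um2,
             max_area_um2 = s$max_area_um2,
             connectivity = s$connectivity)
}

#' Score ROIs on an in-memory image
#'
#' The core orchestration: stain separation, nuclear segmentation,
#' positivity calling, then per-ROI PI scoring and overlay rendering.
#'
#' @param image an [rgb_image()].
#' @param rois list of [roi_polygon()] objects; `NULL` scores the full
#'   frame as a single ROI.
#' @param config a `run_config` (defaults to [default_run_config()]).
#'   The image's own `mpp` is used; the config `mpp` applies only in
#'   [run_score()] where the image comes from a file.
#' @return List with `results` (per-ROI data.frame: roi_id, n_pos,
#'   n_neg, n_total, pi_percent, neg_percent, area_mm2, no_cells),
#'   `nuclei` (per-nucleus table from [classify_nuclei()]), `labels`
#'   (the label matrix), `scores` (list of [score_roi()] objects) and
#'   `overlays` (list of [rgb_image()]).
#' @export
score_image <- function(image, rois = NULL, config = default_run_config()) {
  if (!inherits(image, "rgb_image")) stop("`image` must be an rgb_image")
  sm <- hdab_stain_matrix(config$stains$hematoxylin, config$stains$dab)
  channels <- separate_stains(rgb_to_od(image), sm, mpp = image$mpp)
  labels <- segment_nuclei(channels, config_seg_params(config))
  records <- classify_nuclei(labels, channels$dab,
                             dab_threshold = config$classification$dab_threshold,
                             mpp = image$mpp,
                             statistic = config$classification$statistic)
  if (is.null(rois)) {
    H <- nrow(channels$hematoxylin); W <- ncol(channels$hematoxylin)
    rois <- list(roi_polygon(cbind(c(0, W, W, 0), c(0, 0, H, H)),
                             id = "full-frame"))
  }
  scores <- list(); overlays <- list()
  for (p in rois) {
    mask <- rasterize_roi(p, dim(channels$hematoxylin))
    area <- roi_area_mm2(p, image$mpp)
    scores[[p$id]] <- score_roi(records, mask, roi_id = p$id,
                                area_mm2 = area)
    overlays[[p$id]] <- render_overlay(image, labels, records, mask)
  }
  results <- do.call(rbind, lapply(scores, function(s) {
    data.frame(roi_id = s$roi_id, n_pos = s$n_pos, n_neg = s$n_neg,
               n_total = s$n_total,
               pi_percent = round(s$pi_percent, 1),
               neg_percent = round(s$neg_percent, 1),
               area_mm2 = s$area_mm2, no_cells = s$no_cells,
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  list(results = results, nuclei = records, labels = labels,
       scores = scores, overlays = overlays)
}

#' Score an image file against its ROI annotations
#'
#' File-level wrapper around [score_image()]: reads the image and
#' GeoJSON annotations, runs the pipeline, and writes `results.csv`,
#' `nuclei.csv`, one overlay PNG per ROI, and `run_manifest.json`
#' recording the parameters and output files.
#'
#' @param image_path PNG/TIFF image file.
#' @param annotations_path GeoJSON ROI file, or `NULL` for a full-frame
#'   ROI.
#' @param output_dir output directory (created if needed).
#' @param config a `run_config`; `config$mpp` supplies the image
#'   resolution.
#' @return Invisibly, the [score_image()] result list.
#' @export
run_score <- function(image_path, annotations_path = NULL, output_dir,
                      config = default_run_config()) {
  image <- read_image_rgb(image_path, mpp = config$mpp)
  rois <- if (is.null(annotations_path)) NULL
          else read_roi_annotations(annotations_path)
  res <- score_image(image, rois, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results_csv <- file.path(output_dir, "results.csv")
  nuclei_csv <- file.path(output_dir, "nuclei.csv")
  write.csv(res$results, results_csv, row.names = FALSE)
  write.csv(res$nuclei, nuclei_csv, row.names = FALSE)
  overlay_files <- character(0)
  for (id in names(res$overlays)) {
    f <- file.path(output_dir, sprintf("overlay_%s.png", id))
    write_image_rgb(res$overlays[[id]], f)
    overlay_files <- c(overlay_files, f)
  }
  manifest <- list(
    package = "ki67pi",
    version = as.character(utils::packageVersion("ki67pi")),
    inputs = list(image = image_path,
                  annotations = annotations_path %||% "full-frame"),
    config = unclass(config),
    outputs = c(results_csv, nuclei_csv, overlay_files))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
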