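#' Read and write class maps
#'
#' A class map is stored as a single-channel 8-bit PNG (codes 0..255)
#' next to a JSON legend (`<path>.json`) recording class names, sentinel
#' codes and the microns-per-pixel.
#'
#' @param cmap A `class_map`.
#' @param path PNG path.
#' @return `write_class_map()` the path, invisibly; `read_class_map()` a
#'   `class_map`.
#' @export
write_class_map <- function(cmap, path) {
  png::writePNG(cmap$codes / 255, path)
  jsonlite::write_json(list(legend = cmap$legend,
                            sentinels = as.list(sentinel_codes()),
                            mpp = cmap$mpp),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  codes <- round(png::readPNG(path) * 255)
  storage.mode(codes) <- "integer"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  class_map(codes, meta$legend, mpp = meta$mpp)
}

#' Read and write integer label rasters
#'
#' Ground-truth and superpixel label rasters are stored as single-channel
#' 16-bit TIFFs (supports up to 65535 labels).
#'
#' @param labels Integer matrix.
#' @param path TIFF path.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  out <- round(x * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write a superpixel map (label TIFF + JSON sidecar)
#'
#' @param spmap A `superpixel_map`.
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @export
write_superpixel_map <- function(spmap, path) {
  write_label_tiff(spmap$labels, path)
  jsonlite::write_json(list(background_ids = spmap$background_ids,
                            k = spmap$k, config = unclass(spmap$cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-superpixel labelling table as CSV
#' @param labeling A `superpixel_labeling`.
#' @param path CSV path.
#' @export
write_labeling_csv <- function(labeling, path) {
  utils::write.csv(as.data.frame(labeling), path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report (JSON) and confusion matrix (CSV)
#' @param report A `metrics_report`.
#' @param cm A `confusion_matrix`.
#' @param path Output path (JSON for the report, CSV for the matrix).
#' @param class_names Column/row names for the matrix CSV.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy, total = report$total,
                            per_class = report$per_class),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_confusion_csv <- function(cm, path, class_names = NULL) {
  m <- as.data.frame(unclass(cm))
  if (!is.null(class_names)) {
    names(m) <- class_names
    rownames(m) <- class_names
  }
  utils::write.csv(m, path, row.names = !is.null(class_names))
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()] and
#' [superpixel_config()] (the latter nested under `superpixel:`); a 3x3
#' `stain_matrix:` array may override the H&E default. Unknown keys are
#' an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("downsample", "white_threshold", "stain_matrix", "superpixel",
             "patch_size", "coverage_threshold", "patch_limit", "seed",
             "classes", "rejection_threshold", "closing_radius",
             "opening_radius", "margin_width_um", "batch_size")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- y[setdiff(names(y), c("stain_matrix", "superpixel", "classes"))]
  if (!is.null(y$stain_matrix))
    args$stain <- stain_matrix(matrix(unlist(y$stain_matrix), 3, 3,
                                      byrow = TRUE))
  if (!is.null(y$superpixel))
    args$superpixel <- do.call(superpixel_config, y$superpixel)
  if (!is.null(y$classes))
    args$classes <- setNames(seq_along(y$classes), unlist(y$classes))
  do.call(pipeline_config, args)
}
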