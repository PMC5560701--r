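# File interchange: TIFF rasters (via the tiff package) with JSON sidecars
# carrying geotransform / legend / dates, and GeoJSON for polygons.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a label map as an 8-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the legend, the nodata code (255)
#' and the geotransform.
#'
#' @param labels A [label_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "label_image"))
  m <- labels$labels
  m[is.na(m)] <- 255L
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8)
  jsonlite::write_json(
    list(legend = as.list(labels$legend), nodata = 255,
         geotransform = labels$geotransform),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- round(tiff::readTIFF(path) * 255)
  storage.mode(m) <- "integer"
  m[m == meta$nodata] <- NA_integer_
  legend <- unlist(meta$legend)
  storage.mode(legend) <- "integer"
  label_image(m, legend, meta$geotransform)
}

#' Write a confidence or feature plane as 32-bit float TIFF
#'
#' Values must lie in `[0, 1]`; `NA` is stored as 0 with a mask page.
#'
#' @param m Numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(m, path) {
  mask <- !is.na(m)
  m[!mask] <- 0
  tiff::writeTIFF(list(m, mask * 1), path, bits.per.sample = 32)
  invisible(path)
}

#' Write a scene bundle to a directory
#'
#' Reflectance as one 4-channel 32-bit TIFF per date, the validity mask as
#' a multi-page TIFF, the truth map via [write_label_tiff()], field and
#' stratum polygons as GeoJSON, and `scene.json` with dates, grid and seed.
#'
#' @param bundle A `scene_bundle` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param outdated Optional outdated [label_image()] to store alongside.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(bundle, dir, outdated = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  D <- dim(bundle$stack$reflectance)[3]
  for (d in seq_len(D))
    tiff::writeTIFF(lapply(1:4, function(b) bundle$stack$reflectance[, , d, b]),
                    file.path(dir, sprintf("refl_%03d.tif", d)),
                    bits.per.sample = 32)
  tiff::writeTIFF(lapply(seq_len(D), function(d) bundle$stack$valid[, , d] * 1),
                  file.path(dir, "valid.tif"), bits.per.sample = 8)
  write_label_tiff(bundle$truth, file.path(dir, "truth.tif"))
  if (!is.null(outdated))
    write_label_tiff(outdated, file.path(dir, "outdated.tif"))
  write_fields_geojson(bundle$fields, bundle$stack$geotransform,
                       file.path(dir, "fields.geojson"))
  strata_rect <- data.frame(row0 = 1, row1 = nrow(bundle$strata),
                            col0 = bundle$strata_table$col0,
                            col1 = bundle$strata_table$col1,
                            class = bundle$strata_table$stratum,
                            field_id = bundle$strata_table$stratum)
  write_fields_geojson(strata_rect, bundle$stack$geotransform,
                       file.path(dir, "strata.geojson"))
  jsonlite::write_json(
    list(dates = bundle$stack$dates,
         geotransform = bundle$stack$geotransform,
         width = ncol(bundle$truth$labels), height = nrow(bundle$truth$labels),
         stratum_count = bundle$config$stratum_count,
         seed = bundle$config$seed),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @return List with `stack`, `truth`, `strata` (id matrix) and, when
#'   present, `outdated`.
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  D <- length(meta$dates)
  H <- meta$height; W <- meta$width
  refl <- array(0, c(H, W, D, 4))
  for (d in seq_len(D)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("refl_%03d.tif", d)),
                            all = TRUE)
    for (b in 1:4) refl[, , d, b] <- pages[[b]]
  }
  vpages <- tiff::readTIFF(file.path(dir, "valid.tif"), all = TRUE)
  valid <- array(FALSE, c(H, W, D))
  for (d in seq_len(D)) valid[, , d] <- vpages[[d]] > 0.5
  truth <- read_label_tiff(file.path(dir, "truth.tif"))
  strata <- matrix(1L, H, W)
  sj <- jsonlite::read_json(file.path(dir, "strata.geojson"),
                            simplifyVector = FALSE)
  for (f in sj$features) {
    b <- f$properties
    strata[b$row0:b$row1, b$col0:b$col1] <- as.integer(b$class)
  }
  out <- list(stack = obs_stack(refl, valid, meta$dates, meta$geotransform),
              truth = truth, strata = strata)
  if (file.exists(file.path(dir, "outdated.tif")))
    out$outdated <- read_label_tiff(file.path(dir, "outdated.tif"))
  out
}

# Rectangle table -> GeoJSON FeatureCollection (pixel rectangles mapped
# through the geotransform; row/col bounds also kept as properties).
write_fields_geojson <- function(fields, geotransform, path) {
  gt <- geotransform
  to_xy <- function(row, col) c(gt[1] + (col - 1) * gt[2],
                                gt[3] + (row - 1) * gt[4])
  feats <- lapply(seq_len(nrow(fields)), function(i) {
    f <- fields[i, ]
    p1 <- to_xy(f$row0 - 0.5, f$col0 - 0.5)
    p2 <- to_xy(f$row0 - 0.5, f$col1 + 0.5)
    p3 <- to_xy(f$row1 + 0.5, f$col1 + 0.5)
    p4 <- to_xy(f$row1 + 0.5, f$col0 - 0.5)
    list(type = "Feature",
         properties = list(field_id = f$field_id, class = f$class,
                           row0 = f$row0, row1 = f$row1,
                           col0 = f$col0, col1 = f$col1),
         geometry = list(type = "Polygon",
                         coordinates = list(list(p1, p2, p3, p4, p1))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
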