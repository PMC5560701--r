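# Spectral-temporal features: per-pixel composites of the reflectance time
# series keyed to NDVI phenology. Twelve bands: median reflectance plus mean
# reflectance over the lowest and highest NDVI deciles, for each of red,
# nir, swir1, swir2.

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)`, elementwise. A zero denominator (both bands
#' zero) is flagged invalid (`NA`).
#'
#' @param red,nir Reflectance in `[0, 1]` (vectors/arrays, recycled).
#' @return NDVI in `[-1, 1]`, `NA` where undefined.
#' @export
compute_ndvi <- function(red, nir) {
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectance must be non-negative")
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Extract the 12-band spectral-temporal feature image
#'
#' For every pixel, using its valid observations only: `med.*` is the
#' per-band median; `minNDVI.*` the per-band mean over observations whose
#' NDVI falls in the lowest decile of that pixel's NDVI values (inclusive of
#' the empirical 0.1-quantile, so the decile is never empty); `maxNDVI.*`
#' the same for the highest decile. Observations with undefined NDVI are
#' excluded from decile selection but still contribute to the medians.
#' Pixels with fewer than `min_valid` observations are nodata, and a nodata
#' value in any band marks the whole pixel nodata (classification needs the
#' full 12-vector).
#'
#' @param stack An [obs_stack()].
#' @param min_valid Minimum number of clear observations per pixel.
#' @return A `feature_image`: list with `features` (`[row, col, 12]` array,
#'   band names `med.red` ... `maxNDVI.swir2`), `n_valid` matrix,
#'   `geotransform`.
#' @export
extract_features <- function(stack, min_valid = 3) {
  stopifnot(inherits(stack, "obs_stack"))
  if (min_valid < 1) stop("min_valid must be >= 1")
  d <- dim(stack$reflectance)
  if (d[3] == 0) stop("stack has zero dates")
  H <- d[1]; W <- d[2]; D <- d[3]
  npix <- H * W
  band_mat <- function(b) {
    m <- stack$reflectance[, , , b, drop = FALSE]
    dim(m) <- c(npix, D)
    m
  }
  vm <- stack$valid
  dim(vm) <- c(npix, D)
  out <- composites_cpp(band_mat(1), band_mat(2), band_mat(3), band_mat(4),
                        vm, as.integer(min_valid))
  feats <- out[, 1:12, drop = FALSE]
  # whole-pixel nodata if any feature band is missing
  bad <- !complete.cases(feats)
  feats[bad, ] <- NA_real_
  features <- array(feats, c(H, W, 12),
                    dimnames = list(NULL, NULL, FEATURE_BANDS))
  structure(list(features = features,
                 n_valid = matrix(as.integer(out[, 13]), H, W),
                 geotransform = stack$geotransform),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_image> %d x %d pixels, 12 bands, %d nodata pixels\n",
              d[1], d[2], sum(is.na(x$features[, , 1]))))
  invisible(x)
}

#' @export
dim.feature_image <- function(x) dim(x$features)[1:2]

#' Flatten a feature image to a pixel-by-feature matrix
#'
#' @param fi A `feature_image`.
#' @return `npix x 12` numeric matrix (column names = feature bands); rows in
#'   column-major pixel order.
#' @export
feature_matrix <- function(fi) {
  d <- dim(fi$features)
  m <- fi$features
  dim(m) <- c(d[1] * d[2], 12)
  colnames(m) <- FEATURE_BANDS
  m
}
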