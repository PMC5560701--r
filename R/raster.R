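# Lightweight in-memory raster containers. All grids are row x col matrices
# (row 1 = northernmost line); nodata is NA. A geotransform attribute
# c(x0, dx, y0, dy) ties pixel (i, j) to map coordinates.

#' Construct a label image
#'
#' A categorical raster with a legend. Nodata cells are `NA`.
#'
#' @param labels Integer matrix; values must be codes of `legend` or `NA`.
#' @param legend Named integer vector (name -> class code).
#' @param geotransform Numeric length-4 `c(x0, dx, y0, dy)`.
#' @return A `label_image` object.
#' @export
label_image <- function(labels, legend = scene_legend(),
                        geotransform = c(0, 1, 0, -1)) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  vals <- unique(labels[!is.na(labels)])
  if (length(setdiff(vals, legend)) > 0)
    stop("labels contain codes absent from the legend")
  structure(list(labels = labels, legend = legend,
                 geotransform = as.numeric(geotransform)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$legend, labels = names(x$legend)))
  cat(sprintf("<label_image> %d x %d, %d classes present, %d nodata\n",
              nrow(x$labels), ncol(x$labels), sum(tab > 0),
              sum(is.na(x$labels))))
  print(tab[tab > 0])
  invisible(x)
}

#' @export
dim.label_image <- function(x) dim(x$labels)

#' Construct an observation stack
#'
#' Per-pixel reflectance time series with a validity mask.
#'
#' @param reflectance 4-d array `[row, col, date, band]`, bands ordered
#'   red, nir, swir1, swir2, reflectance in `[0, 1]`.
#' @param valid Logical array `[row, col, date]`; `FALSE` marks observations
#'   lost to clouds/shadows/quality flags.
#' @param dates Strictly increasing numeric vector of observation times.
#' @param geotransform Numeric length-4.
#' @return An `obs_stack` object.
#' @export
obs_stack <- function(reflectance, valid, dates,
                      geotransform = c(0, 1, 0, -1)) {
  d <- dim(reflectance)
  if (length(d) != 4 || d[4] != 4)
    stop("reflectance must be a [row, col, date, 4] array")
  if (!identical(dim(valid), d[1:3]))
    stop("valid mask must match reflectance [row, col, date]")
  if (length(dates) != d[3]) stop("dates length must equal date dimension")
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing")
  r <- reflectance[rep(valid, 4)]
  if (any(!is.finite(r)) || any(r < 0 | r > 1))
    stop("valid reflectance must be finite and in [0, 1]")
  dimnames(reflectance) <- list(NULL, NULL, NULL, STACK_BANDS)
  structure(list(reflectance = reflectance, valid = valid,
                 dates = as.numeric(dates),
                 geotransform = as.numeric(geotransform)),
            class = "obs_stack")
}

#' @export
print.obs_stack <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<obs_stack> %d x %d pixels, %d dates, 4 bands (%.1f%% valid)\n",
              d[1], d[2], d[3], 100 * mean(x$valid)))
  invisible(x)
}

#' @export
dim.obs_stack <- function(x) dim(x$reflectance)[1:2]

# Shift a matrix by (di, dj), padding with NA. Used by all moving-window ops.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(m[1][NA], nr, nc)
  si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
  oki <- si >= 1 & si <= nr; okj <- sj >= 1 & sj <= nc
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

# Binary dilation with a 3x3 (8-connected) element, `iterations` times.
dilate_mask <- function(mask, iterations = 1) {
  for (k in seq_len(iterations)) {
    acc <- mask
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      s <- shift_matrix(mask, di, dj)
      s[is.na(s)] <- FALSE
      acc <- acc | s
    }
    mask <- acc
  }
  mask
}
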