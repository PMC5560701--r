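# Speckle removal on classified maps: conventional majority filter and a
# confidence-weighted variant whose votes are ERP values normalized within
# each moving window, plus binarization to cropland / non-cropland.

# Shared moving-window vote engine. weights = NULL gives unit votes
# (conventional majority). Votes of nodata labels (or NA weights) are
# excluded from both the sum and the normalization. Ties keep the centre
# label; a nodata centre stays nodata. Windows are truncated at the borders.
window_vote_filter <- function(labels_mat, weights_mat = NULL, window = 3) {
  if (window %% 2 == 0 || window < 1) stop("window size must be odd")
  r <- (window - 1) / 2
  classes <- sort(unique(labels_mat[!is.na(labels_mat)]))
  if (length(classes) == 0) return(labels_mat)
  H <- nrow(labels_mat); W <- ncol(labels_mat)
  scores <- lapply(classes, function(k) matrix(0, H, W))
  total <- matrix(0, H, W)
  for (di in -r:r) for (dj in -r:r) {
    sl <- shift_matrix(labels_mat, di, dj)
    w <- if (is.null(weights_mat)) {
      as.numeric(!is.na(sl))
    } else {
      sw <- shift_matrix(weights_mat, di, dj)
      sw[is.na(sw) | is.na(sl)] <- 0
      sw
    }
    total <- total + w
    for (ki in seq_along(classes)) {
      hit <- !is.na(sl) & sl == classes[ki]
      scores[[ki]] <- scores[[ki]] + w * hit
    }
  }
  # normalize window votes to sum 1 (does not move the argmax; kept for
  # fidelity to the weight definition)
  pos <- total > 0
  for (ki in seq_along(classes)) scores[[ki]][pos] <- scores[[ki]][pos] / total[pos]

  best <- matrix(1L, H, W)
  bestscore <- scores[[1]]
  nmax <- matrix(1L, H, W)
  if (length(classes) > 1) for (ki in 2:length(classes)) {
    s <- scores[[ki]]
    tie <- s == bestscore
    gt <- s > bestscore
    nmax[tie] <- nmax[tie] + 1L
    nmax[gt] <- 1L
    best[gt] <- ki
    bestscore[gt] <- s[gt]
  }
  out <- matrix(classes[best], H, W)
  keep_centre <- nmax > 1 | !pos # tie, or no votes at all
  out[keep_centre] <- labels_mat[keep_centre]
  out[is.na(labels_mat)] <- NA
  out
}

#' Conventional 3x3 majority filter
#'
#' Replaces each pixel by the most frequent label among the non-nodata
#' members of its moving window (the centre votes too). Ties keep the
#' centre label; a nodata centre stays nodata; windows are truncated at the
#' image border.
#'
#' @param labels A [label_image()].
#' @param window Odd window size (default 3).
#' @return The filtered [label_image()].
#' @export
majority_filter <- function(labels, window = 3) {
  stopifnot(inherits(labels, "label_image"))
  out <- window_vote_filter(labels$labels, NULL, window)
  label_image(out, labels$legend, labels$geotransform)
}

#' Confidence-weighted 3x3 majority filter
#'
#' Like [majority_filter()], but each window member votes with its ERP
#' confidence, normalized within the window to sum 1: the winning class
#' maximizes the summed normalized confidence of its members. Low-confidence
#' speckle is overruled by confident neighbours even when it is locally in
#' the majority. With equal confidences the filter reduces exactly to the
#' conventional majority filter.
#'
#' @param labels A [label_image()].
#' @param confidence Numeric matrix of ERP values in `[0, 1]` on the same
#'   grid.
#' @param window Odd window size (default 3).
#' @return The filtered [label_image()].
#' @export
weighted_majority_filter <- function(labels, confidence, window = 3) {
  stopifnot(inherits(labels, "label_image"))
  if (!all(dim(confidence) == dim(labels$labels)))
    stop("labels and confidence must share the grid")
  cv <- confidence[!is.na(confidence)]
  if (any(cv < 0 | cv > 1))
    stop("confidence values must lie in [0, 1]")
  out <- window_vote_filter(labels$labels, confidence, window)
  label_image(out, labels$legend, labels$geotransform)
}

#' Binarize a land cover map to cropland / non-cropland
#'
#' @param labels A [label_image()].
#' @param cropland_classes Class codes counted as cropland (default:
#'   cropland and irrigated cropland).
#' @return A binary [label_image()] with legend
#'   `c(non_cropland = 0, cropland = 1)`; nodata preserved.
#' @export
binarize <- function(labels, cropland_classes = CROPLAND_CLASSES) {
  stopifnot(inherits(labels, "label_image"))
  if (length(cropland_classes) == 0) stop("cropland class set is empty")
  if (length(setdiff(cropland_classes, labels$legend)) > 0)
    stop("cropland_classes must be legend classes")
  m <- labels$labels
  out <- matrix(NA_integer_, nrow(m), ncol(m))
  out[!is.na(m)] <- as.integer(m[!is.na(m)] %in% cropland_classes)
  label_image(out, c(non_cropland = 0L, cropland = 1L), labels$geotransform)
}
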