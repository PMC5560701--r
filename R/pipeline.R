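# End-to-end map update: features -> per-stratum harvesting and random
# forest -> buffered prediction -> geometric-mean fusion -> ERP confidence
# -> weighted majority filtering -> binary cropland map.

# Zero-pad a membership image onto a common class set.
expand_membership <- function(m, classes_full) {
  d <- dim(m$memberships)
  k <- length(classes_full)
  out <- array(0, c(d[1], d[2], k))
  cov <- !is.na(m$memberships[, , 1])
  out[!as.vector(cov)] <- NA_real_ # recycled over class planes
  pos <- match(m$classes, classes_full)
  for (j in seq_along(pos)) {
    plane <- out[, , pos[j]]
    plane[cov] <- m$memberships[, , j][cov]
    out[, , pos[j]] <- plane
  }
  structure(list(memberships = out, classes = as.integer(classes_full),
                 geotransform = m$geotransform),
            class = "membership_image")
}

#' Update a cropland map from a reflectance stack and an outdated map
#'
#' Runs the full classification scheme: 12-band spectral-temporal feature
#' extraction; per stratum, reliable-pixel harvesting from the outdated map
#' and a 500-tree random forest; membership prediction over the stratum
#' buffered by `buffer_px` pixels; geometric-mean fusion of overlapping
#' stratum maps; ERP confidence; confidence-weighted majority filtering;
#' binarization to cropland / non-cropland.
#'
#' @param stack An [obs_stack()].
#' @param outdated A [label_image()] sharing the grid (the noisy label
#'   source).
#' @param strata Integer matrix of stratum ids, or `NULL` for a single
#'   stratum.
#' @param seed Integer seed driving all stochastic steps.
#' @param min_valid Minimum clear observations per pixel.
#' @param buffer_px Stratum buffer (pixels) for seamless fusion.
#' @param n_total Training rows per stratum.
#' @param filter_mode `"weighted"` (default), `"majority"` or `"none"`.
#' @param cropland_classes Codes binarized to cropland.
#' @param ... Passed to [harvest_training_set()].
#' @return A `cropland_map` list: `features`, `models`, fused `memberships`,
#'   `erp`, raw `labels`, `labels_filtered`, `binary`, per-stratum Gini
#'   `importance` matrix, and the training sets.
#' @export
map_cropland <- function(stack, outdated, strata = NULL, seed = 1,
                         min_valid = 3, buffer_px = 8, n_total = 5000,
                         filter_mode = c("weighted", "majority", "none"),
                         cropland_classes = CROPLAND_CLASSES, ...) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(inherits(stack, "obs_stack"), inherits(outdated, "label_image"))
  features <- extract_features(stack, min_valid = min_valid)
  H <- dim(features)[1]; W <- dim(features)[2]
  if (is.null(strata)) strata <- matrix(1L, H, W)
  sids <- sort(unique(as.vector(strata)))

  models <- list(); memberships <- list(); trainings <- list()
  for (s in sids) {
    core <- strata == s
    lab_s <- outdated$labels
    lab_s[!core] <- NA_integer_
    outdated_s <- label_image(lab_s, outdated$legend, outdated$geotransform)
    res <- tryCatch({
      training <- harvest_training_set(features, outdated_s,
                                       n_total = n_total, stratum = s,
                                       seed = seed + 97L * s, ...)
      model <- train_stratum_rf(training, seed = seed + 131L * s)
      mem <- predict_memberships(model, features, core, buffer_px = buffer_px)
      list(training = training, model = model, mem = mem)
    }, error = function(e) {
      warning(sprintf("stratum %s skipped: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    key <- as.character(s)
    models[[key]] <- res$model
    memberships[[key]] <- res$mem
    trainings[[key]] <- res$training
  }
  if (length(models) == 0) stop("no stratum produced a usable model")

  classes_full <- sort(unique(unlist(lapply(models, `[[`, "classes"))))
  expanded <- lapply(memberships, expand_membership, classes_full)
  fused <- if (length(expanded) == 1) expanded[[1]]
           else suppressWarnings(fuse_memberships(expanded))
  erp <- compute_erp_image(fused)
  labels <- argmax_label(fused, legend = outdated$legend)
  filtered <- switch(filter_mode,
    weighted = weighted_majority_filter(labels, erp),
    majority = majority_filter(labels),
    none = labels)
  binary <- binarize(filtered, cropland_classes)

  importance <- do.call(rbind, lapply(models, `[[`, "importance"))
  rownames(importance) <- names(models)

  structure(list(features = features, models = models,
                 memberships = fused, erp = erp, labels = labels,
                 labels_filtered = filtered, binary = binary,
                 importance = importance, trainings = trainings,
                 strata = strata),
            class = "cropland_map")
}

#' @export
print.cropland_map <- function(x, ...) {
  d <- dim(x$binary$labels)
  frac <- mean(x$binary$labels == 1L, na.rm = TRUE)
  cat(sprintf("<cropland_map> %d x %d, %d strata, %.1f%% cropland\n",
              d[1], d[2], length(x$models), 100 * frac))
  invisible(x)
}
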