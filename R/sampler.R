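# Training-label harvesting from an outdated land cover map: boundary
# erosion, SOM cluster purity, per-class confidence-interval filtering, and
# proportional sub-sampling that maximizes intra-class dissimilarity.

#' Erode class boundaries of a label map
#'
#' For each class independently, any pixel 8-adjacent to a different label,
#' to nodata, or to the outside of the image becomes nodata; interiors are
#' unchanged. Guards the training pool against imperfect co-registration at
#' field boundaries.
#'
#' @param labels A [label_image()].
#' @return A [label_image()] with boundary pixels set to nodata.
#' @export
erode_class_boundaries <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  m <- labels$labels
  keep <- !is.na(m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- shift_matrix(m, di, dj)
    keep <- keep & !is.na(s) & s == m
  }
  keep[is.na(keep)] <- FALSE
  out <- m
  out[!keep] <- NA_integer_
  label_image(out, labels$legend, labels$geotransform)
}

# Per-cluster membership bookkeeping for one focal class.
cluster_purity <- function(is_focal, assignment) {
  k <- sort(unique(assignment))
  size <- as.vector(table(factor(assignment, levels = k)))
  n_focal <- as.vector(rowsum(as.numeric(is_focal),
                              factor(assignment, levels = k)))
  data.frame(cluster = k, size = size, n_focal = n_focal,
             purity = n_focal / size)
}

#' Select reliable pixels of one class from an outdated map
#'
#' Draws up to `n_class` pixels labeled `class_c` and up to `n_other` pixels
#' from the remaining classes (without replacement, seeded), clusters the
#' merged sample on the 12 spectral-temporal features with a SOM, and flags
#' as reliable every sampled `class_c` pixel whose cluster purity (fraction
#' of `class_c` members in the cluster) reaches `purity_threshold`.
#' `outdated` is expected to be boundary-eroded already (see
#' [erode_class_boundaries()]).
#'
#' @param features A `feature_image`.
#' @param outdated A [label_image()] on the same grid.
#' @param class_c Focal class code.
#' @param n_class,n_other Sample caps (5,000 / 10,000 by default).
#' @param purity_threshold Minimum cluster purity, default 0.75.
#' @param som_shape,som_iter Passed to [cluster_features()].
#' @param seed Integer RNG seed.
#' @return List with `mask` (logical matrix of reliable pixels), `summary`
#'   (per-cluster size / focal count / purity), and `sampled` (the drawn
#'   pixels with cluster and reliability flags).
#' @export
select_reliable <- function(features, outdated, class_c,
                            n_class = 5000, n_other = 10000,
                            purity_threshold = 0.75,
                            som_shape = NULL, som_iter = 10, seed = 1) {
  stopifnot(inherits(features, "feature_image"),
            inherits(outdated, "label_image"))
  H <- dim(features)[1]; W <- dim(features)[2]
  if (!all(dim(outdated$labels) == c(H, W)))
    stop("features and outdated map must share the grid")
  fm <- feature_matrix(features)
  ok <- complete.cases(fm) & !is.na(as.vector(outdated$labels))
  lab <- as.vector(outdated$labels)
  idx_c <- which(ok & lab == class_c)
  empty <- list(mask = matrix(FALSE, H, W), summary = NULL,
                sampled = NULL)
  if (length(idx_c) == 0) {
    warning(sprintf("class %s absent after erosion; empty reliable set",
                    class_c))
    return(empty)
  }
  idx_o <- which(ok & lab != class_c)
  local_seed(seed, {
    pick_c <- resample(idx_c, min(n_class, length(idx_c)))
    pick_o <- if (length(idx_o) > 0)
      resample(idx_o, min(n_other, length(idx_o))) else integer(0)
    pick <- c(pick_c, pick_o)
    is_focal <- c(rep(TRUE, length(pick_c)), rep(FALSE, length(pick_o)))
    assignment <- cluster_features(fm[pick, , drop = FALSE],
                                   som_shape = som_shape, n_iter = som_iter,
                                   seed = seed)
    summary <- cluster_purity(is_focal, assignment)
    pur <- summary$purity[match(assignment, summary$cluster)]
    reliable <- is_focal & pur >= purity_threshold
    mask <- matrix(FALSE, H, W)
    mask[pick[reliable]] <- TRUE
    list(mask = mask, summary = summary,
         sampled = data.frame(index = pick, is_focal = is_focal,
                              cluster = assignment, purity = pur,
                              reliable = reliable))
  })
}

#' Drop rows outside the per-band 95% interval of their class
#'
#' Removes rows falling outside the empirical `[2.5, 97.5]` percentile
#' interval of the class in any of the 12 feature bands. With fewer than 20
#' rows the filter passes everything through (with a warning): the interval
#' would be meaningless.
#'
#' @param rows Data frame containing the feature band columns.
#' @param feature_cols Column names to screen.
#' @return The filtered data frame.
#' @export
filter_ci <- function(rows, feature_cols = FEATURE_BANDS) {
  if (nrow(rows) < 20) {
    warning("fewer than 20 rows; confidence-interval filter skipped")
    return(rows)
  }
  keep <- rep(TRUE, nrow(rows))
  for (cc in feature_cols) {
    q <- quantile(rows[[cc]], c(0.025, 0.975), names = FALSE)
    keep <- keep & rows[[cc]] >= q[1] & rows[[cc]] <= q[2]
  }
  rows[keep, , drop = FALSE]
}

# largest-remainder apportionment of n_total among proportions
quota_round <- function(proportions, n_total) {
  raw <- proportions * n_total
  base <- floor(raw)
  need <- n_total - sum(base)
  if (need > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Greedy farthest-point (max-min) subset of `quota` rows in standardized
# feature space, seeded at the row nearest the centroid. Deterministic.
farthest_point_subset <- function(X, quota, center, scale) {
  n <- nrow(X)
  if (quota >= n) return(seq_len(n))
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  centroid <- colMeans(Xs)
  d0 <- rowSums(sweep(Xs, 2, centroid)^2)
  sel <- integer(quota)
  sel[1] <- which.min(d0)
  mind <- rowSums(sweep(Xs, 2, Xs[sel[1], ])^2)
  mind[sel[1]] <- -Inf
  if (quota > 1) for (i in 2:quota) {
    sel[i] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(Xs, 2, Xs[sel[i], ])^2))
    mind[sel[i]] <- -Inf
  }
  sel
}

#' Assemble the stratum training set from reliable pixels
#'
#' Per-class quotas regain the prescribed class proportions
#' (largest-remainder rounding so quotas sum to `n_total`); within each
#' class, rows are chosen by greedy max-min (farthest-point) selection in
#' standardized feature space to maximize intra-class dissimilarity. A class
#' with fewer reliable rows than its quota contributes everything it has
#' (the total may then fall below `n_total`).
#'
#' @param reliable_by_class Named list (class code -> data.frame of reliable
#'   rows with `row`, `col` and the 12 feature columns).
#' @param proportions Named numeric (class code -> proportion), summing to 1
#'   over the classes present.
#' @param n_total Target sample size (default 5,000).
#' @param stratum Stratum id recorded on the rows.
#' @param seed Integer seed (selection is deterministic; kept for API
#'   symmetry).
#' @return A `training_set` data.frame: row, col, stratum, class, the 12
#'   feature bands, and provenance flags.
#' @export
build_training_set <- function(reliable_by_class, proportions,
                               n_total = 5000, stratum = 1L, seed = 1) {
  counts <- vapply(reliable_by_class, nrow, integer(1))
  if (all(counts == 0)) stop("no reliable rows in any class")
  cls <- names(proportions)
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1 over classes present")
  quotas <- quota_round(proportions, n_total)
  names(quotas) <- cls

  pooled <- do.call(rbind, lapply(reliable_by_class,
                                  function(d) as.matrix(d[, FEATURE_BANDS])))
  center <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1

  out <- list()
  for (k in cls) {
    rows_k <- reliable_by_class[[k]]
    if (is.null(rows_k) || nrow(rows_k) == 0) next
    q <- quotas[[k]]
    if (q == 0) next
    sel <- farthest_point_subset(as.matrix(rows_k[, FEATURE_BANDS]),
                                 q, center, scl)
    chosen <- rows_k[sel, , drop = FALSE]
    chosen$class <- as.integer(k)
    out[[k]] <- chosen
  }
  res <- do.call(rbind, out)
  res$stratum <- as.integer(stratum)
  res$reliable <- TRUE
  rownames(res) <- NULL
  class(res) <- c("training_set", "data.frame")
  res
}

#' Harvest a full training set for one stratum
#'
#' Convenience wrapper running the whole harvesting chain: boundary erosion
#' of the outdated map, per-class reliable-pixel selection by SOM cluster
#' purity, the per-class 95% interval filter, class proportions computed
#' from the eroded map, and proportional max-min sub-sampling down to
#' `n_total` rows.
#'
#' @param features A `feature_image`.
#' @param outdated A [label_image()] (not yet eroded).
#' @param n_total Target training-set size.
#' @param stratum Stratum id recorded on the rows.
#' @param proportions Optional named class proportions overriding those
#'   derived from the eroded outdated map.
#' @param ... Passed to [select_reliable()] (sample caps, purity threshold,
#'   SOM settings).
#' @param seed Integer RNG seed.
#' @return A `training_set` data.frame (see [build_training_set()]).
#' @export
harvest_training_set <- function(features, outdated, n_total = 5000,
                                 stratum = 1L, proportions = NULL,
                                 seed = 1, ...) {
  eroded <- erode_class_boundaries(outdated)
  present <- sort(unique(as.vector(eroded$labels)))
  present <- present[!is.na(present)]
  if (length(present) == 0) stop("eroded outdated map is empty")
  H <- dim(features)[1]
  fm <- feature_matrix(features)
  reliable_by_class <- list()
  for (k in present) {
    sr <- select_reliable(features, eroded, k, seed = seed + k, ...)
    idx <- which(sr$mask)
    if (length(idx) == 0) next
    d <- data.frame(row = ((idx - 1) %% H) + 1,
                    col = ((idx - 1) %/% H) + 1)
    d <- cbind(d, as.data.frame(fm[idx, , drop = FALSE]))
    d <- filter_ci(d)
    if (nrow(d) > 0) reliable_by_class[[as.character(k)]] <- d
  }
  if (length(reliable_by_class) == 0)
    stop("no reliable rows in any class")
  kept <- as.integer(names(reliable_by_class))
  if (is.null(proportions)) {
    tab <- table(factor(as.vector(eroded$labels), levels = kept))
    proportions <- as.numeric(tab) / sum(tab)
    names(proportions) <- kept
  } else {
    proportions <- proportions[as.character(kept)]
    proportions <- proportions / sum(proportions)
  }
  build_training_set(reliable_by_class, proportions, n_total = n_total,
                     stratum = stratum, seed = seed)
}
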