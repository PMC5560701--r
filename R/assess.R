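# Accuracy assessment: global confusion-matrix scores, spatially
# constrained local accuracy with IDW interpolation, confidence-separation
# testing, and Friedman/Nemenyi ranking of feature importances.

#' Confusion matrix and accuracy scores
#'
#' Counts over pixels valid in both maps. Overall accuracy `OA` with its
#' binomial standard error `sqrt(OA (1 - OA) / N)`; per class, user's
#' accuracy (precision), producer's accuracy (recall) and the F-score
#' `2 UA PA / (UA + PA)`. With `erode_edges = TRUE` the reference map is
#' boundary-eroded first (see [erode_class_boundaries()]), discarding mixed
#' edge pixels from the evaluation.
#'
#' @param predicted,reference [label_image()]s on the same grid.
#' @param erode_edges Drop reference boundary pixels before counting.
#' @return An `accuracy_report`: confusion matrix (rows = predicted),
#'   `oa`, `se_oa`, `n`, per-class table, and `fs_c` / `fs_nc` when the
#'   maps are binary cropland maps.
#' @export
confusion_and_scores <- function(predicted, reference, erode_edges = FALSE) {
  stopifnot(inherits(predicted, "label_image"),
            inherits(reference, "label_image"))
  if (!all(dim(predicted$labels) == dim(reference$labels)))
    stop("predicted and reference must share the grid")
  if (erode_edges) reference <- erode_class_boundaries(reference)
  p <- as.vector(predicted$labels)
  r <- as.vector(reference$labels)
  ok <- !is.na(p) & !is.na(r)
  n <- sum(ok)
  if (n == 0) stop("no jointly valid pixels")
  classes <- sort(union(unique(p[ok]), unique(r[ok])))
  cm <- table(predicted = factor(p[ok], levels = classes),
              reference = factor(r[ok], levels = classes))
  oa <- sum(diag(cm)) / n
  ua <- diag(cm) / rowSums(cm)
  pa <- diag(cm) / colSums(cm)
  fs <- 2 * ua * pa / (ua + pa)
  per_class <- data.frame(class = classes, ua = as.numeric(ua),
                          pa = as.numeric(pa), f_score = as.numeric(fs))
  rep <- list(confusion = cm, oa = oa, se_oa = sqrt(oa * (1 - oa) / n),
              n = n, per_class = per_class)
  if (all(classes %in% c(0L, 1L))) {
    rep$fs_c <- per_class$f_score[match(1L, classes)]
    rep$fs_nc <- per_class$f_score[match(0L, classes)]
  }
  structure(rep, class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, OA = %.4f (SE %.2e)\n",
              x$n, x$oa, x$se_oa))
  if (!is.null(x$fs_c))
    cat(sprintf("  FS_cropland = %.4f, FS_non_cropland = %.4f\n",
                x$fs_c, x$fs_nc))
  invisible(x)
}

# binary accuracy scores on plain vectors (local windows)
binary_scores <- function(p, r) {
  n <- length(p)
  oa <- mean(p == r)
  fs_of <- function(cls) {
    tp <- sum(p == cls & r == cls)
    ua <- tp / sum(p == cls)
    pa <- tp / sum(r == cls)
    2 * ua * pa / (ua + pa)
  }
  c(oa = oa, fs_c = fs_of(1L), fs_nc = fs_of(0L))
}

#' Spatially constrained local accuracy surface
#'
#' Lays a regular grid of evaluation points `spacing` apart; at each point,
#' accuracy scores are computed from the jointly valid pixels inside a
#' centred square window of side `window`. Points with fewer than
#' `min_count` reference pixels are masked. The point scores are
#' interpolated to a full raster by inverse-distance weighting (power 2),
#' exact at the point locations.
#'
#' @param predicted,reference Binary [label_image()]s on the same grid.
#' @param spacing Grid-point spacing in pixels.
#' @param window Square window side in pixels (>= 1).
#' @param min_count Minimum reference-pixel count per window.
#' @return List with `points` (data.frame of row, col, n, oa, fs_c, fs_nc)
#'   and `surface` (list of interpolated matrices).
#' @export
local_accuracy <- function(predicted, reference, spacing, window,
                           min_count = 500) {
  stopifnot(inherits(predicted, "label_image"),
            inherits(reference, "label_image"))
  if (spacing <= 0) stop("spacing must be positive")
  if (window < 1) stop("window must cover at least one pixel")
  pm <- predicted$labels; rm_ <- reference$labels
  if (!all(dim(pm) == dim(rm_))) stop("grids differ")
  H <- nrow(pm); W <- ncol(pm)
  half <- floor(window / 2)
  rows <- seq(ceiling(spacing / 2), H, by = spacing)
  cols <- seq(ceiling(spacing / 2), W, by = spacing)
  pts <- expand.grid(row = rows, col = cols)
  res <- matrix(NA_real_, nrow(pts), 4)
  for (i in seq_len(nrow(pts))) {
    ri <- max(1, pts$row[i] - half):min(H, pts$row[i] + half)
    ci <- max(1, pts$col[i] - half):min(W, pts$col[i] + half)
    p <- as.vector(pm[ri, ci]); r <- as.vector(rm_[ri, ci])
    ok <- !is.na(p) & !is.na(r)
    res[i, 1] <- sum(ok)
    if (sum(ok) >= min_count)
      res[i, 2:4] <- binary_scores(p[ok], r[ok])
  }
  points <- data.frame(row = pts$row, col = pts$col, n = res[, 1],
                       oa = res[, 2], fs_c = res[, 3], fs_nc = res[, 4])
  surface <- list(
    oa = idw_surface(points$row, points$col, points$oa, H, W),
    fs_c = idw_surface(points$row, points$col, points$fs_c, H, W),
    fs_nc = idw_surface(points$row, points$col, points$fs_nc, H, W))
  list(points = points, surface = surface, spacing = spacing,
       window = window, min_count = min_count)
}

# Inverse-distance-weighted (power 2) interpolation of point values onto the
# full grid; exact at point locations; masked (NA) points are dropped.
idw_surface <- function(prow, pcol, vals, H, W) {
  keep <- !is.na(vals)
  if (!any(keep)) return(matrix(NA_real_, H, W))
  prow <- prow[keep]; pcol <- pcol[keep]; vals <- vals[keep]
  gi <- rep(seq_len(H), times = W)
  gj <- rep(seq_len(W), each = H)
  num <- numeric(H * W); den <- numeric(H * W)
  exact <- rep(NA_real_, H * W)
  for (k in seq_along(vals)) {
    d2 <- (gi - prow[k])^2 + (gj - pcol[k])^2
    at <- d2 == 0
    exact[at] <- vals[k]
    w <- 1 / d2
    w[at] <- 0
    num <- num + w * vals[k]
    den <- den + w
  }
  out <- num / den
  out[!is.na(exact)] <- exact[!is.na(exact)]
  matrix(out, H, W)
}

#' Do well-classified cropland pixels carry higher confidence?
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test comparing the ERP of
#' correctly vs incorrectly classified pixels of the focal class (cropland
#' by default, judged against the reference map). If both groups are a
#' single tied constant, the midrank convention gives p = 1.
#'
#' @param confidence ERP matrix.
#' @param predicted,reference [label_image()]s on the same grid.
#' @param class Focal class code in the reference legend.
#' @param min_n Group size below which a warning is emitted.
#' @return List: `applicable`, group sizes, `statistic`, `p_value`,
#'   `direction` (`"correct_higher"` / `"incorrect_higher"` / `"none"`).
#' @export
confidence_separation <- function(confidence, predicted, reference,
                                  class = 1L, min_n = 20) {
  stopifnot(inherits(predicted, "label_image"),
            inherits(reference, "label_image"))
  p <- as.vector(predicted$labels)
  r <- as.vector(reference$labels)
  cf <- as.vector(confidence)
  sel <- !is.na(p) & !is.na(r) & !is.na(cf) & r == class
  correct <- cf[sel & p == class]
  incorrect <- cf[sel & p != class]
  if (length(correct) == 0 || length(incorrect) == 0)
    return(list(applicable = FALSE, n_correct = length(correct),
                n_incorrect = length(incorrect), statistic = NA_real_,
                p_value = NA_real_, direction = "none"))
  if (length(correct) < min_n || length(incorrect) < min_n)
    warning("fewer than ", min_n, " pixels in a group")
  if (length(unique(c(correct, incorrect))) == 1) {
    stat <- length(correct) * length(incorrect) / 2
    pval <- 1
  } else {
    wt <- suppressWarnings(wilcox.test(correct, incorrect,
                                       alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
    stat <- unname(wt$statistic)
    pval <- wt$p.value
  }
  dmed <- median(correct) - median(incorrect)
  list(applicable = TRUE, n_correct = length(correct),
       n_incorrect = length(incorrect), statistic = stat, p_value = pval,
       direction = if (dmed > 0) "correct_higher"
                   else if (dmed < 0) "incorrect_higher" else "none")
}

#' Friedman test and Nemenyi critical difference on feature importances
#'
#' Features are ranked within each stratum (midranks for ties, rank 1 =
#' most important); the tie-corrected Friedman chi-squared tests whether
#' the features are equally important across strata. The post-hoc Nemenyi
#' critical difference is `q_{alpha,k,df} / sqrt(2) * sqrt(k (k + 1) / (6 N))`
#' with `q` from the studentized-range distribution (`df = Inf` by default);
#' pairs of features whose mean ranks differ by at least CD are flagged.
#'
#' @param importance Numeric matrix, strata (rows) x features (columns).
#' @param alpha Significance level for the critical difference.
#' @param df Degrees of freedom for the studentized-range quantile.
#' @return List: `statistic`, `df_chisq`, `p_value`, `mean_ranks`, `cd`,
#'   `pairwise_significant` (logical matrix), `ranks`.
#' @export
feature_importance_stats <- function(importance, alpha = 0.05, df = Inf) {
  importance <- as.matrix(importance)
  if (any(!is.finite(importance))) stop("importances must be finite")
  N <- nrow(importance); k <- ncol(importance)
  if (N < 2 || k < 2) stop("need at least 2 strata and 2 features")
  ranks <- t(apply(importance, 1, function(x) rank(-x))) # rank 1 = best
  Rj <- colSums(ranks)
  raw <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  tie_sum <- sum(apply(ranks, 1, function(rr) {
    t <- table(rr)
    sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (N * k * (k^2 - 1))
  stat <- if (C <= 0) 0 else raw / C
  cd <- qtukey(1 - alpha, k, df) / sqrt(2) * sqrt(k * (k + 1) / (6 * N))
  mean_ranks <- Rj / N
  if (!is.null(colnames(importance))) names(mean_ranks) <- colnames(importance)
  diffs <- abs(outer(mean_ranks, mean_ranks, "-"))
  list(statistic = stat, df_chisq = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE),
       mean_ranks = mean_ranks, cd = cd,
       pairwise_significant = diffs >= cd, ranks = ranks, alpha = alpha)
}
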