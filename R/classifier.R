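# Stratum-specific classification: probability random forests on the 12
# spectral-temporal features, geometric-mean fusion of overlapping stratum
# maps, entropy-consistent confidence (equivalent reference probability),
# and hard labeling by maximum membership.

#' Train a stratum random forest
#'
#' 500 trees, `floor(sqrt(12)) = 3` candidate split variables per node,
#' probability (tree-vote fraction) output and Gini impurity importance.
#'
#' @param training A `training_set` data.frame with `class` and the 12
#'   feature columns.
#' @param seed Integer seed (forest growth is deterministic given it).
#' @param num_trees,mtry Forest size and split candidates.
#' @return A `stratum_rf`: list with the fitted ranger model, the sorted
#'   class codes, out-of-bag accuracy and Gini importances.
#' @export
train_stratum_rf <- function(training, seed = 1, num_trees = 500,
                             mtry = NULL) {
  classes <- sort(unique(training$class))
  if (length(classes) < 2)
    stop("training set must contain at least two classes")
  if (is.null(mtry)) mtry <- floor(sqrt(length(FEATURE_BANDS)))
  dat <- training[, FEATURE_BANDS, drop = FALSE]
  dat$class <- factor(training$class, levels = classes)
  model <- ranger::ranger(
    dependent.variable.name = "class", data = dat,
    num.trees = num_trees, mtry = mtry, probability = TRUE,
    importance = "impurity", seed = seed, num.threads = 1)
  oob <- model$predictions # rows x classes, OOB vote fractions
  oob_lab <- classes[max.col(oob, ties.method = "first")]
  oob_ok <- stats::complete.cases(oob)
  structure(list(model = model, classes = as.integer(classes),
                 oob_accuracy = mean(oob_lab[oob_ok] ==
                                       training$class[oob_ok]),
                 importance = model$variable.importance),
            class = "stratum_rf")
}

#' @export
print.stratum_rf <- function(x, ...) {
  cat(sprintf("<stratum_rf> %d trees, %d classes, OOB accuracy %.3f\n",
              x$model$num.trees, length(x$classes), x$oob_accuracy))
  invisible(x)
}

#' Predict per-pixel class memberships for a (buffered) stratum
#'
#' Produces the forest's vote distribution for every feature-complete pixel
#' inside the stratum mask dilated by `buffer_px` pixels (the buffer lets
#' neighbouring stratum maps overlap so fusion can smooth stratum seams);
#' everything outside is nodata.
#'
#' @param model A `stratum_rf`.
#' @param features A `feature_image` with the same 12 bands the model was
#'   trained on (mismatched band names are an error).
#' @param stratum_mask Logical matrix, or `NULL` for the whole image.
#' @param buffer_px Mask dilation radius in pixels.
#' @return A `membership_image`: `[row, col, n_classes]` probability array
#'   (each non-nodata vector sums to 1), sorted class codes, geotransform.
#' @export
predict_memberships <- function(model, features, stratum_mask = NULL,
                                buffer_px = 0) {
  stopifnot(inherits(model, "stratum_rf"),
            inherits(features, "feature_image"))
  want <- model$model$forest$independent.variable.names
  if (!identical(sort(want), sort(FEATURE_BANDS)))
    stop("model feature bands do not match the 12-band feature definition")
  H <- dim(features)[1]; W <- dim(features)[2]
  mask <- if (is.null(stratum_mask)) matrix(TRUE, H, W)
          else if (buffer_px > 0) dilate_mask(stratum_mask, buffer_px)
          else stratum_mask
  fm <- feature_matrix(features)
  ok <- complete.cases(fm) & as.vector(mask)
  k <- length(model$classes)
  mem <- matrix(NA_real_, H * W, k)
  if (any(ok)) {
    pred <- predict(model$model, data = as.data.frame(fm[ok, , drop = FALSE]),
                    num.threads = 1)$predictions
    # ranger orders columns by factor level = sorted class code
    mem[ok, ] <- pred
  }
  arr <- array(mem, c(H, W, k))
  structure(list(memberships = arr, classes = model$classes,
                 geotransform = features$geotransform),
            class = "membership_image")
}

#' @export
print.membership_image <- function(x, ...) {
  d <- dim(x$memberships)
  cat(sprintf("<membership_image> %d x %d pixels, %d classes, %d covered\n",
              d[1], d[2], d[3], sum(!is.na(x$memberships[, , 1]))))
  invisible(x)
}

#' Fuse overlapping stratum membership maps
#'
#' Pixels covered by a single source are copied; pixels covered by several
#' get the componentwise geometric mean of the covering membership vectors,
#' renormalized to sum 1. Zero memberships are floored at `eps` before the
#' mean so a single zero vote cannot annihilate a class.
#'
#' @param sources List of `membership_image`s with identical class order.
#' @param eps Zero floor applied before the geometric mean.
#' @return A fused `membership_image` (nodata where no source covers).
#' @export
fuse_memberships <- function(sources, eps = 1e-6) {
  stopifnot(length(sources) >= 1)
  cls <- sources[[1]]$classes
  for (s in sources)
    if (!identical(s$classes, cls))
      stop("all sources must share the same class order")
  d <- dim(sources[[1]]$memberships)
  H <- d[1]; W <- d[2]; k <- d[3]
  sumlog <- array(0, d)
  cnt <- matrix(0L, H, W)
  for (s in sources) {
    cov <- !is.na(s$memberships[, , 1])
    cnt <- cnt + cov
    m <- pmax(s$memberships, eps)
    lg <- log(m)
    lg[is.na(lg)] <- 0
    sumlog <- sumlog + lg
  }
  gm <- exp(sumlog / as.vector(cnt)) # recycled over classes
  dim(gm) <- c(H * W, k)
  fused <- gm / rowSums(gm)
  fused[as.vector(cnt) == 0, ] <- NA_real_
  dim(fused) <- d
  # single coverage: copy the source vector verbatim (no eps distortion)
  for (s in sources) {
    cov <- !is.na(s$memberships[, , 1]) & cnt == 1
    if (any(cov)) {
      sel <- as.vector(cov)
      for (j in seq_len(k)) {
        plane <- fused[, , j]
        plane[sel] <- s$memberships[, , j][sel]
        fused[, , j] <- plane
      }
    }
  }
  if (any(cnt == 0))
    warning(sprintf("%d pixels covered by no source (nodata)", sum(cnt == 0)))
  structure(list(memberships = fused, classes = cls,
                 geotransform = sources[[1]]$geotransform),
            class = "membership_image")
}

# Entropy of the reference distribution: one class at M, the remaining mass
# uniform over n-1 classes. Strictly decreasing in M on [1/n, 1].
reference_entropy <- function(M, n) {
  a <- ifelse(M > 0, -M * log(M), 0)
  q <- (1 - M) / (n - 1)
  b <- ifelse(q > 0, -(1 - M) * log(q), 0)
  a + b
}

shannon_entropy <- function(p) {
  terms <- ifelse(p > 0, -p * log(p), 0)
  sum(terms)
}

#' Equivalent reference probability of a membership vector
#'
#' Maps a probability vector `p` to the scalar `M` in `[1/n, 1]` such that
#' the reference distribution (one class at `M`, the remaining mass uniform
#' over the other `n - 1` classes) has the same Shannon entropy as `p`.
#' Accounts for the full probability set while agreeing with `max(p)`
#' whenever `p` is itself reference-shaped; confident pixels score close
#' to 1, maximally ambiguous ones `1/n`. Solved by bisection.
#'
#' @param p Probability vector (must sum to 1), `n >= 2`.
#' @param tol Bisection tolerance.
#' @return ERP value in `[1/n, 1]`.
#' @export
compute_erp <- function(p, tol = 1e-8) {
  n <- length(p)
  if (n < 2) stop("need at least two classes")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a probability vector summing to 1")
  H <- shannon_entropy(p)
  lo <- 1 / n; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (reference_entropy(mid, n) > H) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-pixel ERP confidence image
#'
#' Vectorized [compute_erp()] over a membership image.
#'
#' @param memberships A `membership_image`.
#' @param tol Bisection tolerance.
#' @return Numeric matrix of ERP values in `[1/n, 1]` (`NA` at nodata).
#' @export
compute_erp_image <- function(memberships, tol = 1e-8) {
  d <- dim(memberships$memberships)
  n <- d[3]
  m <- memberships$memberships
  dim(m) <- c(d[1] * d[2], n)
  ok <- complete.cases(m)
  out <- rep(NA_real_, d[1] * d[2])
  if (any(ok)) {
    P <- m[ok, , drop = FALSE]
    Hp <- rowSums(ifelse(P > 0, -P * log(P), 0))
    lo <- rep(1 / n, nrow(P)); hi <- rep(1, nrow(P))
    iters <- ceiling(log2(1 / tol)) + 1
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      go_up <- reference_entropy(mid, n) > Hp
      lo[go_up] <- mid[go_up]
      hi[!go_up] <- mid[!go_up]
    }
    out[ok] <- (lo + hi) / 2
  }
  matrix(out, d[1], d[2])
}

#' Hard labels from a membership image
#'
#' Per pixel, the class of maximal membership; exact ties go to the lowest
#' class code (the number of ties is recorded in attribute `"n_ties"`).
#'
#' @param memberships A `membership_image`.
#' @param legend Legend for the output [label_image()].
#' @return A [label_image()] (nodata where memberships are nodata).
#' @export
argmax_label <- function(memberships, legend = scene_legend()) {
  d <- dim(memberships$memberships)
  m <- memberships$memberships
  dim(m) <- c(d[1] * d[2], d[3])
  ok <- complete.cases(m)
  out <- rep(NA_integer_, d[1] * d[2])
  n_ties <- 0L
  if (any(ok)) {
    sub <- m[ok, , drop = FALSE]
    best <- max.col(sub, ties.method = "first") # classes sorted ascending
    rowmax <- sub[cbind(seq_len(nrow(sub)), best)]
    n_ties <- sum(rowSums(sub == rowmax) > 1)
    out[ok] <- memberships$classes[best]
  }
  res <- label_image(matrix(out, d[1], d[2]), legend,
                     memberships$geotransform)
  attr(res, "n_ties") <- n_ties
  res
}
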