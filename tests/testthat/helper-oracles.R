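# Independent oracles and tiny fixtures used across the suite.

# Brute-force per-window majority / weighted-majority evaluator, written as
# a direct loop over window members: score_i = sum of (normalized) weights
# of members with label i; ties keep the centre label.
brute_force_filter <- function(labels, weights = NULL, window = 3) {
  H <- nrow(labels); W <- ncol(labels)
  r <- (window - 1) / 2
  out <- labels
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (is.na(labels[i, j])) next
    ri <- max(1, i - r):min(H, i + r)
    ci <- max(1, j - r):min(W, j + r)
    ls <- as.vector(labels[ri, ci])
    ws <- if (is.null(weights)) rep(1, length(ls))
          else as.vector(weights[ri, ci])
    ok <- !is.na(ls) & !is.na(ws)
    ls <- ls[ok]; ws <- ws[ok]
    if (length(ls) == 0 || sum(ws) == 0) next # keep centre
    ws <- ws / sum(ws)
    score <- tapply(ws, ls, sum)
    mx <- max(score)
    winners <- as.integer(names(score)[score == mx])
    out[i, j] <- if (length(winners) > 1) labels[i, j] else winners
  }
  out
}

# Naive per-pixel composite extraction (R loop) mirroring the documented
# definition; the independent check for the compiled path.
naive_composites <- function(stack, min_valid = 3) {
  d <- dim(stack$reflectance)
  out <- array(NA_real_, c(d[1], d[2], 12))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- which(stack$valid[i, j, ])
    if (length(v) < min_valid) next
    bands <- stack$reflectance[i, j, v, , drop = TRUE]
    if (is.null(dim(bands))) bands <- matrix(bands, nrow = 1)
    med <- apply(bands, 2, median)
    red <- bands[, 1]; nir <- bands[, 2]
    den <- red + nir
    ndvi <- ifelse(den > 0, (nir - red) / den, NA)
    use <- !is.na(ndvi)
    if (!any(use)) next
    q <- quantile(ndvi[use], c(0.1, 0.9), names = FALSE)
    lo <- use & ndvi <= q[1]
    hi <- use & ndvi >= q[2]
    out[i, j, ] <- c(med,
                     colMeans(bands[lo, , drop = FALSE]),
                     colMeans(bands[hi, , drop = FALSE]))
  }
  out
}

bin_leg <- c(non_cropland = 0L, cropland = 1L)

# binary prediction/reference maps realizing a given confusion matrix
maps_from_counts <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  side <- ceiling(sqrt(n))
  pred <- ref <- rep(NA_integer_, side^2)
  pred[1:n] <- c(rep(1L, tp), rep(0L, fn), rep(1L, fp), rep(0L, tn))
  ref[1:n]  <- c(rep(1L, tp), rep(1L, fn), rep(0L, fp), rep(0L, tn))
  list(pred = label_image(matrix(pred, side, side), bin_leg),
       ref = label_image(matrix(ref, side, side), bin_leg))
}

# A small label map with a given legend, from a matrix literal.
toy_labels <- function(m, legend = scene_legend()) {
  label_image(m, legend)
}

# Membership image wrapper around a plain pixel x class probability matrix.
toy_membership <- function(probs, H, W, classes = seq_len(ncol(probs))) {
  arr <- array(probs, c(H, W, ncol(probs)))
  structure(list(memberships = arr, classes = as.integer(classes),
                 geotransform = c(0, 1, 0, -1)),
            class = "membership_image")
}

# Gaussian-profile feature matrix for classifier tests: class centroids
# `centers` (k x 12), n rows per class, noise sd `sd`.
separable_features <- function(centers, n_per_class, sd = 0.02, seed = 1) {
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(c_) {
    matrix(rnorm(n_per_class * ncol(centers), mean = centers[c_, ], sd = sd),
           n_per_class, ncol(centers), byrow = TRUE)
  }))
  colnames(X) <- freshmap:::FEATURE_BANDS
  d <- as.data.frame(X)
  d$class <- rep(seq_len(k), each = n_per_class)
  d$row <- seq_len(nrow(d)); d$col <- 1L
  set.seed(seed)
  d[sample(nrow(d)), ]
}

# Exhaustive permutation null of the Friedman statistic for k treatments,
# N blocks (continuous data: all k! within-block rank orders equally
# likely). Returns the sorted null distribution of the statistic.
friedman_permutation_null <- function(k, N, stat_fun) {
  perms <- matrix(unlist(combinat_permn(seq_len(k))), ncol = k, byrow = TRUE)
  idx <- as.matrix(do.call(expand.grid,
                           rep(list(seq_len(nrow(perms))), N)))
  apply(idx, 1, function(ix) stat_fun(perms[ix, , drop = FALSE]))
}

# all permutations of a small vector (no external dependency)
combinat_permn <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_permn(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

# tie-corrected Friedman statistic computed from a rank matrix (blocks x k)
friedman_stat_from_ranks <- function(R) {
  N <- nrow(R); k <- ncol(R)
  Rj <- colSums(R)
  raw <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  ties <- sum(apply(R, 1, function(rr) { t <- table(rr); sum(t^3 - t) }))
  C <- 1 - ties / (N * k * (k^2 - 1))
  if (C <= 0) 0 else raw / C
}
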