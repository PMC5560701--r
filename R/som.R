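# Small deterministic batch self-organizing map used for spectral
# clustering. Gaussian neighbourhood on a rectangular node grid, radius
# decaying linearly across iterations; codebook initialized from a seeded
# sample of the data.

som_fit <- function(X, grid, n_iter = 10, seed = 1) {
  n <- nrow(X); p <- ncol(X)
  k <- prod(grid)
  if (k > n) stop("SOM grid has more nodes than samples")
  coords <- as.matrix(expand.grid(gx = seq_len(grid[1]), gy = seq_len(grid[2])))
  D2 <- as.matrix(dist(coords))^2

  W <- local_seed(seed, {
    init <- X[resample(seq_len(n), k), , drop = FALSE]
    # tiny jitter breaks exact duplicates in the initial codebook
    init + matrix(rnorm(k * p, sd = 1e-6), k, p)
  })

  x2 <- rowSums(X^2)
  bmu_of <- function(W) {
    # argmin_k ||x - w_k||^2 == argmax_k (x.w_k - ||w_k||^2 / 2)
    score <- X %*% t(W) - rep(rowSums(W^2) / 2, each = n)
    max.col(score, ties.method = "first")
  }

  r0 <- max(grid) / 2
  radii <- seq(max(r0, 0.3), 0.3, length.out = n_iter)
  for (it in seq_len(n_iter)) {
    bmu <- bmu_of(W)
    h <- exp(-D2 / (2 * radii[it]^2))
    Sp <- rowsum(X, bmu) # one row per occupied node
    S <- matrix(0, k, p)
    S[as.integer(rownames(Sp)), ] <- Sp
    cnt <- tabulate(bmu, k)
    denom <- as.vector(h %*% cnt)
    upd <- denom > 1e-12
    W[upd, ] <- (h %*% S)[upd, , drop = FALSE] / denom[upd]
  }
  bmu <- bmu_of(W)
  list(codebook = W, assignment = bmu, grid = grid, coords = coords)
}

#' Cluster feature vectors with a self-organizing map
#'
#' Features are standardized internally; each row is assigned to its
#' best-matching SOM node. The default grid follows the ~5*sqrt(n) node
#' rule of thumb, capped at 16 x 16. Deterministic under a fixed seed.
#'
#' @param X Numeric matrix (rows = samples).
#' @param som_shape Integer length-2 grid, or `NULL` for the default.
#' @param n_iter Batch training iterations.
#' @param seed Integer RNG seed.
#' @return Integer vector of cluster (node) assignments, with the fitted
#'   SOM attached as attribute `"som"`.
#' @export
cluster_features <- function(X, som_shape = NULL, n_iter = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("empty sample")
  if (is.null(som_shape)) {
    target <- max(1, min(ceiling(5 * sqrt(n)), 256, n))
    gx <- max(1, floor(sqrt(target)))
    gy <- max(1, floor(target / gx))
    som_shape <- c(gx, gy)
  }
  if (prod(som_shape) > n)
    stop("som_shape larger than the sample size")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fit <- som_fit(Xs, as.integer(som_shape), n_iter = n_iter, seed = seed)
  structure(fit$assignment, som = fit)
}
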