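# Reliable-pixel harvesting: boundary erosion, SOM clustering, cluster
# purity, the 95% interval filter, and proportional max-min sub-sampling.

test_that("erosion removes boundary pixels as hand-derived", {
  leg <- scene_legend()
  # isolated single pixel disappears
  m <- matrix(5L, 7, 7); m[4, 4] <- 1L
  e <- erode_class_boundaries(toy_labels(m))
  expect_true(is.na(e$labels[4, 4]))
  # 3x3 block: only the centre survives (plus background interior)
  m <- matrix(5L, 9, 9); m[4:6, 4:6] <- 1L
  e <- erode_class_boundaries(toy_labels(m))
  inblock <- e$labels[4:6, 4:6]
  expect_equal(sum(!is.na(inblock)), 1L)
  expect_equal(inblock[2, 2], 1L)
  # homogeneous image keeps everything but the outer frame
  m <- matrix(3L, 8, 8)
  e <- erode_class_boundaries(toy_labels(m))
  expect_true(all(is.na(e$labels[1, ])) && all(is.na(e$labels[, 8])))
  expect_true(all(e$labels[2:7, 2:7] == 3L))
})

test_that("SOM assignments agree with k-means on separated blobs", {
  set.seed(1)
  X <- rbind(matrix(rnorm(300 * 3, 0), 300, 3),
             matrix(rnorm(300 * 3, 6), 300, 3))
  a <- cluster_features(X, som_shape = c(2, 1), seed = 3)
  km <- kmeans(scale(X), centers = 2, nstart = 5)$cluster
  agree <- max(mean((a == 1) == (km == 1)), mean((a == 1) == (km == 2)))
  expect_gte(agree, 0.95)
})

test_that("SOM is deterministic and collapses identical rows", {
  X <- matrix(rnorm(200 * 4), 200, 4)
  a1 <- cluster_features(X, som_shape = c(3, 3), seed = 5)
  a2 <- cluster_features(X, som_shape = c(3, 3), seed = 5)
  expect_identical(as.integer(a1), as.integer(a2))
  same <- matrix(1, 50, 4)
  expect_equal(length(unique(as.integer(
    cluster_features(same, som_shape = c(2, 2), seed = 1)))), 1L)
  expect_error(cluster_features(X[1:3, ], som_shape = c(2, 2)),
               "larger than the sample")
})

test_that("cluster purity flags the 75% threshold inclusively", {
  # cluster of 4 with 3 focal members: purity exactly 0.75 -> reliable
  is_focal <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  assignment <- c(1L, 1L, 1L, 1L, 2L, 2L)
  ps <- freshmap:::cluster_purity(is_focal, assignment)
  expect_equal(ps$purity[ps$cluster == 1], 0.75)
  expect_equal(ps$size, c(4L, 2L))
  expect_equal(sum(ps$size), length(assignment))
})

test_that("clean well-separated maps yield almost all pixels reliable", {
  frac <- sapply(1:5, function(s) {
    b <- generate_scene(scene_config(width = 64, height = 64, n_dates = 12,
                                     cloud_fraction = 0.1, seed = s))
    f <- extract_features(b$stack)
    eroded <- erode_class_boundaries(b$truth)
    cls <- 5L # grassland, always abundant under the default mix
    sr <- select_reliable(f, eroded, cls, seed = s)
    mean(sr$sampled$reliable[sr$sampled$is_focal])
  })
  expect_gte(mean(frac >= 0.95), 0.8)
})

test_that("pixels flipped from a spectrally distinct class come out unreliable", {
  b <- generate_scene(scene_config(width = 64, height = 64, n_dates = 12,
                                   cloud_fraction = 0, seed = 21))
  f <- extract_features(b$stack)
  lab <- b$truth$labels
  # relabel 30% of water pixels as cropland: spectrally distinct flips
  wat <- which(lab == 9L)
  set.seed(2)
  flip <- sample(wat, round(0.3 * length(wat)))
  lab[flip] <- 1L
  sr <- select_reliable(f, label_image(lab), 1L, seed = 3)
  flipped_sampled <- sr$sampled$index %in% flip & sr$sampled$is_focal
  expect_gt(sum(flipped_sampled), 20)
  expect_lt(mean(sr$sampled$reliable[flipped_sampled]), 0.25)
})

test_that("interval filter keeps central rows and drops per-band extremes", {
  set.seed(4)
  n <- 60
  rows <- as.data.frame(matrix(runif(n * 12), n, 12))
  names(rows) <- freshmap:::FEATURE_BANDS
  # append the per-band median row: inside every interval
  med_row <- as.data.frame(as.list(vapply(rows, median, numeric(1))))
  rows2 <- rbind(rows, med_row)
  kept <- filter_ci(rows2)
  expect_true(nrow(kept) < nrow(rows2))
  expect_true(any(apply(kept, 1, function(r)
    all(abs(as.numeric(r) - as.numeric(med_row)) < 1e-12))))
  # the row holding the maximum of band 1 is gone (n > 40 distinct values)
  top <- which.max(rows2[[1]])
  expect_false(top %in% as.integer(rownames(kept)))
  # degenerate: identical rows all survive
  same <- rows2[rep(1, 25), ]
  expect_equal(nrow(filter_ci(same)), 25L)
  # under 20 rows: pass-through with warning
  expect_warning(out <- filter_ci(rows[1:5, ]), "fewer than 20")
  expect_equal(nrow(out), 5L)
})

test_that("interval filter removes at most ~5% per band pair of tails", {
  set.seed(11)
  n <- 4000
  rows <- as.data.frame(matrix(rnorm(n * 12), n, 12))
  names(rows) <- freshmap:::FEATURE_BANDS
  kept <- filter_ci(rows)
  removed <- 1 - nrow(kept) / n
  expect_lte(removed, 12 * 0.05) # union bound over bands
})

test_that("quotas follow largest-remainder rounding on stated proportions", {
  q <- freshmap:::quota_round(c(cropland = 0.2, grassland = 0.8), 5000)
  expect_equal(q, c(1000L, 4000L))
  q2 <- freshmap:::quota_round(c(a = 1 / 3, b = 1 / 3, c = 1 / 3), 100)
  expect_equal(sum(q2), 100L)
})

test_that("training-set assembly honours quotas, duplicates and totals", {
  set.seed(6)
  mk <- function(n, mu) {
    d <- as.data.frame(matrix(rnorm(n * 12, mu), n, 12))
    names(d) <- freshmap:::FEATURE_BANDS
    d$row <- seq_len(n); d$col <- 1L
    d
  }
  rel <- list("1" = mk(300, 0), "5" = mk(300, 3))
  ts <- build_training_set(rel, c("1" = 0.2, "5" = 0.8), n_total = 200)
  expect_equal(as.vector(table(ts$class)), c(40L, 160L))
  # n_total = everything available -> all rows selected
  ts_all <- build_training_set(rel, c("1" = 0.5, "5" = 0.5), n_total = 600)
  expect_equal(nrow(ts_all), 600L)
  # duplicated rows are only picked once distinct rows are exhausted
  base <- mk(10, 0)
  dup <- rbind(base, base[rep(1, 30), ])
  sel <- freshmap:::farthest_point_subset(
    as.matrix(dup[, freshmap:::FEATURE_BANDS]), 10,
    colMeans(base[, freshmap:::FEATURE_BANDS]), rep(1, 12))
  picked <- dup[sel, freshmap:::FEATURE_BANDS]
  expect_equal(nrow(unique(round(picked, 10))), 10L)
  empty <- mk(1, 0)[0, ]
  expect_error(build_training_set(list("1" = empty), c("1" = 1)),
               "no reliable rows")
})

test_that("harvested training sets beat the raw outdated map under 25% flips", {
  gains <- sapply(1:5, function(s) {
    b <- generate_scene(scene_config(width = 96, height = 96, n_dates = 16,
                                     seed = s))
    out <- make_outdated_map(b$truth, flip_rate = 0.25, seed = s + 50)
    raw <- mean(out$labels == b$truth$labels)
    f <- extract_features(b$stack)
    tr <- suppressWarnings(harvest_training_set(f, out, n_total = 5000,
                                                seed = s))
    correct <- mean(tr$class == b$truth$labels[cbind(tr$row, tr$col)])
    100 * (correct - raw)
  })
  expect_gte(sum(gains >= 10), 4)
})
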