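# Accuracy assessment: confusion bookkeeping, spatially constrained local
# accuracy, confidence separation, and Friedman/Nemenyi ranking.

test_that("confusion scores reproduce hand arithmetic", {
  m <- maps_from_counts(40, 10, 20, 930)
  rep <- confusion_and_scores(m$pred, m$ref)
  expect_equal(rep$n, 1000L)
  pc <- rep$per_class
  expect_equal(pc$ua[pc$class == 1], 40 / 60, tolerance = 1e-12)
  expect_equal(pc$pa[pc$class == 1], 40 / 50, tolerance = 1e-12)
  expect_equal(rep$fs_c, 0.727, tolerance = 5e-4)
  expect_equal(rep$oa, 0.97, tolerance = 1e-12)
  expect_equal(rep$se_oa, sqrt(0.97 * 0.03 / 1000), tolerance = 1e-12)
})

test_that("a perfect map scores 1 everywhere", {
  m <- maps_from_counts(50, 0, 0, 950)
  rep <- confusion_and_scores(m$pred, m$pred)
  expect_equal(rep$oa, 1)
  expect_equal(rep$fs_c, 1)
  expect_equal(rep$fs_nc, 1)
})

test_that("swapping maps transposes the matrix and swaps UA/PA", {
  m <- maps_from_counts(40, 10, 20, 930)
  a <- confusion_and_scores(m$pred, m$ref)
  b <- confusion_and_scores(m$ref, m$pred)
  expect_equal(unclass(unname(a$confusion)), t(unclass(unname(b$confusion))))
  expect_equal(a$per_class$ua, b$per_class$pa)
  expect_equal(a$per_class$f_score, b$per_class$f_score)
  expect_equal(a$oa, b$oa)
})

test_that("matrix total conserves the jointly valid pixel count", {
  set.seed(3)
  p <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE), 10, 20)
  r <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE), 10, 20)
  rep <- confusion_and_scores(label_image(p, bin_leg),
                              label_image(r, bin_leg))
  expect_equal(sum(rep$confusion), sum(!is.na(p) & !is.na(r)))
  expect_error(confusion_and_scores(label_image(p, bin_leg),
                                    label_image(matrix(NA_integer_, 10, 20),
                                                bin_leg)),
               "no jointly valid")
})

test_that("edge erosion lifts accuracy when errors sit on boundaries", {
  b <- generate_scene(scene_config(width = 48, height = 48, n_dates = 10,
                                   seed = 17))
  ref <- b$truth
  pred <- ref$labels
  # corrupt exactly the boundary pixels of the reference
  interior <- erode_class_boundaries(ref)
  edge <- which(is.na(interior$labels) & !is.na(ref$labels))
  pred[edge] <- vapply(pred[edge], function(k)
    freshmap:::resample(setdiff(scene_legend(), k), 1), integer(1))
  pred_img <- label_image(pred, scene_legend())
  plain <- confusion_and_scores(pred_img, ref)
  eroded <- confusion_and_scores(pred_img, ref, erode_edges = TRUE)
  expect_lt(plain$oa, 1)
  expect_equal(eroded$oa, 1)
})

test_that("local accuracy is flat under spatially uniform error", {
  set.seed(23)
  H <- 120; W <- 120
  r <- matrix(rbinom(H * W, 1, 0.3), H, W)
  p <- r
  wrong <- runif(H * W) < 0.1
  p[wrong] <- 1L - p[wrong]
  storage.mode(p) <- "integer"; storage.mode(r) <- "integer"
  la <- local_accuracy(label_image(p, bin_leg), label_image(r, bin_leg),
                       spacing = 30, window = 45, min_count = 300)
  glob <- mean(p == r)
  pts <- la$points[!is.na(la$points$oa), ]
  expect_gt(nrow(pts), 4)
  expect_true(all(abs(pts$oa - glob) < 0.05))
  # IDW surface bounded by point extrema and exact at the points
  expect_true(all(la$surface$oa >= min(pts$oa) - 1e-9, na.rm = TRUE))
  expect_true(all(la$surface$oa <= max(pts$oa) + 1e-9, na.rm = TRUE))
  for (i in seq_len(nrow(pts)))
    expect_equal(la$surface$oa[pts$row[i], pts$col[i]], pts$oa[i])
})

test_that("empty windows are masked and localized error shows up locally", {
  H <- 90; W <- 90
  r <- matrix(0L, H, W); r[1:45, 1:45] <- 1L
  p <- r
  set.seed(1)
  # errors confined to the upper-left quadrant
  q <- which(row(r) <= 45 & col(r) <= 45)
  bad <- sample(q, round(0.3 * length(q)))
  p[bad] <- 1L - p[bad]
  ref <- label_image(r, bin_leg); prd <- label_image(p, bin_leg)
  la <- local_accuracy(prd, ref, spacing = 30, window = 30, min_count = 100)
  pts <- la$points
  deep <- pts$row <= 30 & pts$col <= 30       # window wholly inside quadrant
  clean <- pts$row >= 60 | pts$col >= 60      # window cannot touch it
  expect_true(all(pts$oa[deep] < 0.9))
  expect_true(all(pts$oa[clean] == 1))
  # straddling points score between the fully-hit and clean regimes
  mid <- !deep & !clean
  expect_true(all(pts$oa[mid] < 1 & pts$oa[mid] > min(pts$oa[deep])))
  # a window holding no reference pixels is masked
  r2 <- r; r2[, 46:90] <- NA_integer_
  la2 <- local_accuracy(prd, label_image(r2, bin_leg),
                        spacing = 30, window = 30, min_count = 100)
  expect_true(any(is.na(la2$points$oa)))
  expect_error(local_accuracy(prd, ref, spacing = 30, window = 0), "window")
})

test_that("confidence separation behaves under null, extreme and degenerate data", {
  H <- 40; W <- 40
  r <- label_image(matrix(1L, H, W), bin_leg)
  set.seed(31)
  p <- matrix(rbinom(H * W, 1, 0.7), H, W)
  storage.mode(p) <- "integer"
  pimg <- label_image(p, bin_leg)
  # null: both groups from the same distribution -> calibrated rejections
  rejections <- replicate(400, {
    conf <- matrix(runif(H * W), H, W)
    confidence_separation(conf, pimg, r)$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
  # disjoint supports -> overwhelming significance, correct direction
  conf <- matrix(0, H, W)
  conf[p == 1L] <- runif(sum(p == 1L), 0.8, 1)
  conf[p == 0L] <- runif(sum(p == 0L), 0, 0.2)
  res <- confidence_separation(conf, pimg, r)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$direction, "correct_higher")
  # all-tie constants -> p = 1 by the midrank convention
  res2 <- confidence_separation(matrix(0.5, H, W), pimg, r)
  expect_equal(res2$p_value, 1)
  # an empty group -> explicit not-applicable
  perfect <- label_image(matrix(1L, H, W), bin_leg)
  res3 <- confidence_separation(matrix(0.5, H, W), perfect, r)
  expect_false(res3$applicable)
})

test_that("Friedman statistic matches stats::friedman.test without ties", {
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(rnorm(9 * 12), 9, 12)
    mine <- feature_importance_stats(x)
    ref <- friedman.test(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # all features identical within each stratum -> statistic 0
  flat <- matrix(rep(1:4, each = 3), 4, 3)
  flat[] <- 5
  expect_equal(feature_importance_stats(flat)$statistic, 0)
  expect_error(feature_importance_stats(matrix(c(1, Inf, 2, 3), 2, 2)),
               "finite")
})

test_that("Friedman p-values are calibrated against the exact permutation null", {
  k <- 3; N <- 4
  null <- sort(friedman_permutation_null(k, N, friedman_stat_from_ranks))
  set.seed(51)
  reps <- 2000
  pv <- replicate(reps, {
    x <- matrix(rnorm(N * k), N, k)
    s <- feature_importance_stats(x)$statistic
    mean(null >= s - 1e-9)
  })
  # the discrete null admits alpha = 1/24 = 0.0417 at the 0.05 level
  expect_lt(abs(mean(pv <= 0.05) - 0.05), 0.01)
})

test_that("Nemenyi critical difference follows the studentized-range form", {
  x <- matrix(rnorm(9 * 12), 9, 12)
  res <- feature_importance_stats(x, alpha = 0.05, df = Inf)
  expect_equal(res$cd,
               qtukey(0.95, 12, Inf) / sqrt(2) * sqrt(12 * 13 / (6 * 9)),
               tolerance = 1e-12)
  expect_equal(res$cd, 5.5545, tolerance = 1e-4)
  # strongly consistent rankings flag pairs beyond the CD
  prof <- matrix(rep(seq(12, 1), each = 9), 9, 12)
  res2 <- feature_importance_stats(prof + rnorm(108, sd = 1e-6))
  expect_true(res2$pairwise_significant[1, 12])
  expect_false(res2$pairwise_significant[1, 2])
  expect_equal(unname(res2$mean_ranks[1]), 1)
})
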