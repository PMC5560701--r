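# Synthetic agricultural scenes: seeded reflectance time series over a
# field mosaic, plus degraded "outdated" label maps. Everything downstream
# (features, harvesting, classification, filtering, assessment) is exercised
# on these scenes.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Reflectance curves from an NDVI trajectory: nir + red = s (brightness),
# nir - red = s * ndvi.
ndvi_to_rednir <- function(ndvi, s) {
  list(red = s * (1 - ndvi) / 2, nir = s * (1 + ndvi) / 2)
}

#' Default per-class seasonal reflectance profiles
#'
#' Each class follows a sinusoidal NDVI trajectory (class-specific baseline,
#' amplitude and phase); red and NIR are back-computed from the trajectory so
#' the noise-free NDVI of the profile matches it exactly, and the SWIR bands
#' decrease linearly with canopy greenness. Cropland has a high-amplitude
#' curve with a bare-soil minimum (bright red/SWIR at season start),
#' grassland a moderate one, forest an evergreen plateau, water low NIR and
#' negative NDVI throughout.
#'
#' @param dates Numeric observation times in years (seasonality = fractional
#'   part of the year).
#' @return Named list (one entry per legend class) of 4 x length(dates)
#'   matrices with rows red, nir, swir1, swir2.
#' @export
default_class_profiles <- function(dates) {
  t <- dates %% 1
  # per class: ndvi baseline b, amplitude a, phase ph, brightness s,
  # swir1/swir2 maxima and greenness coupling
  par <- list(
    cropland           = list(b = 0.45, a = 0.35, ph = 0.00, s = 0.55,
                              sw1 = 0.32, sw2 = 0.27, cpl = 0.18),
    irrigated_cropland = list(b = 0.55, a = 0.30, ph = 0.15, s = 0.50,
                              sw1 = 0.22, sw2 = 0.16, cpl = 0.12),
    forest             = list(b = 0.80, a = 0.05, ph = 0.00, s = 0.45,
                              sw1 = 0.12, sw2 = 0.07, cpl = 0.03),
    shrubland          = list(b = 0.35, a = 0.10, ph = 0.00, s = 0.45,
                              sw1 = 0.28, sw2 = 0.22, cpl = 0.05),
    grassland          = list(b = 0.45, a = 0.20, ph = 0.00, s = 0.50,
                              sw1 = 0.25, sw2 = 0.20, cpl = 0.07),
    wetland            = list(b = 0.50, a = 0.15, ph = 0.05, s = 0.40,
                              sw1 = 0.10, sw2 = 0.06, cpl = 0.04),
    built_up           = list(b = 0.15, a = 0.00, ph = 0.00, s = 0.60,
                              sw1 = 0.30, sw2 = 0.28, cpl = 0.00),
    bare_soil          = list(b = 0.08, a = 0.00, ph = 0.00, s = 0.62,
                              sw1 = 0.38, sw2 = 0.34, cpl = 0.00),
    water              = list(b = -0.30, a = 0.00, ph = 0.00, s = 0.10,
                              sw1 = 0.02, sw2 = 0.01, cpl = 0.00)
  )
  lapply(par, function(p) {
    ndvi <- p$b - p$a * cos(2 * pi * (t - p$ph))
    rn <- ndvi_to_rednir(ndvi, p$s)
    g <- if (p$a > 0) (ndvi - min(ndvi)) / (max(ndvi) - min(ndvi)) else 0 * ndvi
    m <- rbind(red = rn$red, nir = rn$nir,
               swir1 = p$sw1 - p$cpl * g,
               swir2 = p$sw2 - p$cpl * g)
    pmax(pmin(m, 1), 0)
  })
}

#' Shrink class profiles towards their common mean
#'
#' Utility for studying class separability: `factor = 1` leaves the profiles
#' unchanged, `factor = 0` collapses every class onto the across-class mean
#' curve (classes become spectrally indistinguishable).
#'
#' @param profiles As returned by [default_class_profiles()].
#' @param factor Separation multiplier in `[0, 1]`.
#' @return Profile list of the same shape.
#' @export
scale_profile_separation <- function(profiles, factor) {
  stopifnot(factor >= 0, factor <= 1)
  mean_prof <- Reduce(`+`, profiles) / length(profiles)
  lapply(profiles, function(m) mean_prof + factor * (m - mean_prof))
}

#' Scene generator configuration
#'
#' @param width,height Scene size in pixels (each >= 32).
#' @param n_dates Number of observation dates (>= 10), spread over a
#'   three-year window.
#' @param class_profiles Per-class seasonal reflectance curves; default
#'   [default_class_profiles()] on the generated dates.
#' @param class_mix Named sampling probabilities for field classes.
#' @param noise_sd Per-observation Gaussian reflectance noise (sd).
#' @param cloud_fraction Proportion of (pixel, date) observations flagged
#'   invalid, in `[0, 1)`.
#' @param field_size_range Integer range (pixels) of field edge lengths.
#' @param stratum_count Number of vertical stratum bands.
#' @param seed Integer RNG seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 128, height = 128, n_dates = 24,
                         class_profiles = NULL,
                         class_mix = c(cropland = 0.15, irrigated_cropland = 0.05,
                                       forest = 0.08, shrubland = 0.20,
                                       grassland = 0.30, wetland = 0.05,
                                       built_up = 0.05, bare_soil = 0.07,
                                       water = 0.05),
                         noise_sd = 0.02, cloud_fraction = 0.3,
                         field_size_range = c(6, 20), stratum_count = 1,
                         seed = 1) {
  if (width < 32 || height < 32) stop("width and height must be >= 32")
  if (n_dates < 10) stop("n_dates must be >= 10")
  if (cloud_fraction < 0 || cloud_fraction >= 1)
    stop("cloud_fraction must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(class_mix) == 0 || any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix must be non-negative with positive total")
  legend <- scene_legend()
  if (length(setdiff(names(class_mix), names(legend))) > 0)
    stop("class_mix names must be legend classes")
  dates <- seq(0, 3, length.out = n_dates)
  if (is.null(class_profiles)) class_profiles <- default_class_profiles(dates)
  bad <- vapply(class_profiles,
                function(m) any(!is.finite(m)) || any(m < 0 | m > 1),
                logical(1))
  if (any(bad)) stop("every profile value must be finite and in [0, 1]")
  stopifnot(length(field_size_range) == 2, field_size_range[1] >= 1,
            stratum_count >= 1)
  structure(list(width = width, height = height, n_dates = n_dates,
                 dates = dates, class_profiles = class_profiles,
                 class_mix = class_mix / sum(class_mix),
                 noise_sd = noise_sd, cloud_fraction = cloud_fraction,
                 field_size_range = as.integer(field_size_range),
                 stratum_count = as.integer(stratum_count),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# sample() that never expands a length-1 vector into 1:x
resample <- function(x, ...) x[sample.int(length(x), ...)]

# Cut a length into random segments within `range` (last segment clamped).
random_cuts <- function(total, range) {
  sizes <- integer(0); used <- 0
  while (used < total) {
    s <- resample(seq(range[1], range[2]), 1)
    s <- min(s, total - used)
    sizes <- c(sizes, s); used <- used + s
  }
  sizes
}

#' Generate a synthetic scene
#'
#' Tiles the extent into rectangular fields on a jittered grid, draws a class
#' for each field, builds the per-date reflectance from the class profiles
#' plus Gaussian noise, and knocks out a random fraction of observations as
#' clouds. Identical configs (including seed) give bit-identical bundles.
#'
#' @param config A [scene_config()].
#' @return A `scene_bundle`: list with `stack` ([obs_stack()]), `truth`
#'   ([label_image()]), `fields` (data.frame of field rectangles with class),
#'   `strata` (integer matrix of stratum ids), `strata_table`, `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  H <- config$height; W <- config$width; D <- config$n_dates
  legend <- scene_legend()
  classes <- legend[names(config$class_mix)]
  local_seed(config$seed, {
    # jittered field mosaic: random row bands, then random column cuts per band
    row_sizes <- random_cuts(H, config$field_size_range)
    fields <- list(); truth <- matrix(NA_integer_, H, W)
    r0 <- 1
    for (rs in row_sizes) {
      col_sizes <- random_cuts(W, config$field_size_range)
      c0 <- 1
      for (cs in col_sizes) {
        cls <- resample(classes, 1, prob = config$class_mix)
        truth[r0:(r0 + rs - 1), c0:(c0 + cs - 1)] <- cls
        fields[[length(fields) + 1]] <-
          data.frame(row0 = r0, row1 = r0 + rs - 1,
                     col0 = c0, col1 = c0 + cs - 1, class = cls)
        c0 <- c0 + cs
      }
      r0 <- r0 + rs
    }
    fields <- do.call(rbind, fields)
    fields$field_id <- seq_len(nrow(fields))

    # class profiles -> base reflectance cube [H, W, D, 4]
    prof <- array(0, c(length(legend), 4, D))
    for (nm in names(config$class_profiles)) {
      code <- legend[[nm]]
      prof[code, , ] <- config$class_profiles[[nm]]
    }
    refl <- array(0, c(H, W, D, 4))
    cls_vec <- as.vector(truth)
    for (d in seq_len(D)) for (b in 1:4)
      refl[, , d, b] <- prof[cbind(cls_vec, b, d)]
    if (config$noise_sd > 0) {
      refl <- refl + rnorm(length(refl), sd = config$noise_sd)
      refl <- pmax(pmin(refl, 1), 0)
    }
    valid <- array(runif(H * W * D) >= config$cloud_fraction, c(H, W, D))

    strata <- matrix(rep(as.integer(pmin(config$stratum_count,
                              ceiling(seq_len(W) / (W / config$stratum_count)))),
                         each = H), H, W)
    strata_table <- data.frame(
      stratum = seq_len(config$stratum_count),
      col0 = vapply(seq_len(config$stratum_count),
                    function(s) min(which(strata[1, ] == s)), integer(1)),
      col1 = vapply(seq_len(config$stratum_count),
                    function(s) max(which(strata[1, ] == s)), integer(1)))

    structure(list(stack = obs_stack(refl, valid, config$dates),
                   truth = label_image(truth, legend),
                   fields = fields, strata = strata,
                   strata_table = strata_table, config = config),
              class = "scene_bundle")
  })
}

#' Inject classification speckle into a label map
#'
#' Emulates the error structure of an unfiltered per-pixel classification:
#' isolated single-pixel errors plus small coherent patches of a wrong
#' class (mis-mapped field fragments), together with a synthetic confidence
#' plane in which errors score systematically lower than correct pixels —
#' the premise under which confidence-weighted filtering can outperform
#' plain majority voting.
#'
#' @param truth A [label_image()].
#' @param pixel_rate Fraction of pixels flipped in isolation.
#' @param n_patches Number of coherent wrong-class patches.
#' @param patch_side Side length (pixels) of each square patch.
#' @param conf_correct,conf_error Uniform confidence ranges for correct and
#'   erroneous pixels.
#' @param seed Integer RNG seed.
#' @return List: `labels` (speckled [label_image()]), `confidence` matrix,
#'   `error_mask` logical matrix.
#' @export
inject_speckle <- function(truth, pixel_rate = 0.04, n_patches = 8,
                           patch_side = 3,
                           conf_correct = c(0.80, 0.98),
                           conf_error = c(0.15, 0.55), seed = 1) {
  stopifnot(inherits(truth, "label_image"))
  legend <- truth$legend
  m <- truth$labels
  H <- nrow(m); W <- ncol(m)
  local_seed(seed, {
    err <- matrix(FALSE, H, W)
    idx <- which(!is.na(m))
    k <- round(pixel_rate * length(idx))
    if (k > 0) {
      pick <- resample(idx, k)
      m[pick] <- vapply(m[pick], function(cl)
        resample(setdiff(legend, cl), 1), integer(1))
      err[pick] <- TRUE
    }
    for (p in seq_len(n_patches)) {
      r0 <- resample(seq_len(H - patch_side + 1), 1)
      c0 <- resample(seq_len(W - patch_side + 1), 1)
      rows <- r0:(r0 + patch_side - 1); cols <- c0:(c0 + patch_side - 1)
      cur <- truth$labels[rows, cols]
      avoid <- unique(as.vector(cur))
      if (length(setdiff(legend, avoid)) == 0) avoid <- avoid[1]
      wrong <- resample(setdiff(legend, avoid), 1)
      m[rows, cols] <- wrong
      err[rows, cols] <- TRUE
    }
    conf <- matrix(runif(H * W, conf_correct[1], conf_correct[2]), H, W)
    conf[err] <- runif(sum(err), conf_error[1], conf_error[2])
    conf[is.na(m)] <- NA_real_
    list(labels = label_image(m, legend, truth$geotransform),
         confidence = conf, error_mask = err)
  })
}

#' Degrade a truth map into an "outdated" land cover map
#'
#' Injects the two error types an old map carries: per-pixel classification
#' errors (`flip_rate` of pixels relabeled uniformly to another legend class)
#' and land-cover change (`change_fraction` of whole fields relabeled,
#' spatially coherent).
#'
#' @param truth A [label_image()].
#' @param flip_rate,change_fraction Proportions in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param fields Field rectangle table from [generate_scene()]; required when
#'   `change_fraction > 0`.
#' @return A [label_image()] with the same legend and grid.
#' @export
make_outdated_map <- function(truth, flip_rate = 0, change_fraction = 0,
                              seed = 1, fields = NULL) {
  stopifnot(inherits(truth, "label_image"))
  if (flip_rate < 0 || flip_rate >= 1 || change_fraction < 0 ||
      change_fraction >= 1)
    stop("flip_rate and change_fraction must be in [0, 1)")
  legend <- truth$legend
  if (length(legend) < 2 && flip_rate > 0)
    stop("cannot flip labels: legend has a single class")
  if (change_fraction > 0 && is.null(fields))
    stop("`fields` is required when change_fraction > 0")
  out <- truth$labels
  local_seed(seed, {
    if (change_fraction > 0) {
      n_ch <- round(change_fraction * nrow(fields))
      if (n_ch > 0) {
        chosen <- sample(nrow(fields), n_ch)
        for (f in chosen) {
          fc <- fields$class[f]
          new_cls <- resample(setdiff(legend, fc), 1)
          out[fields$row0[f]:fields$row1[f],
              fields$col0[f]:fields$col1[f]] <- new_cls
        }
      }
    }
    if (flip_rate > 0) {
      idx <- which(!is.na(out))
      k <- round(flip_rate * length(idx))
      if (k > 0) {
        pick <- sample(idx, k)
        cur <- out[pick]
        # uniform draw over the other legend classes
        draw <- sample(length(legend) - 1L, k, replace = TRUE)
        othered <- vapply(seq_len(k), function(i) {
          setdiff(legend, cur[i])[draw[i]]
        }, integer(1))
        out[pick] <- othered
      }
    }
  })
  label_image(out, legend, truth$geotransform)
}
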