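# freshmap

Automated cropland-extent mapping when the only available training labels
come from an **outdated land cover map**. Up-to-date ground truth is the
perennial bottleneck of supervised land cover classification over large
areas; `freshmap` implements a fully automated scheme that harvests still-
reliable pixels from an old map, trains region-specific classifiers on
them, and delivers an updated binary cropland map with a per-pixel
confidence estimate — plus the machinery to validate it, globally and
spatially.

## The method

Given a multi-date surface-reflectance stack (red, NIR, SWIR1, SWIR2 with a
validity mask) and an outdated categorical map on the same grid:

1. **Spectral-temporal features.** Per pixel, twelve composites of the
   valid observations: the per-band median, and the per-band mean over the
   lowest and highest deciles of the pixel's NDVI values
   (`med.*`, `minNDVI.*`, `maxNDVI.*`), NDVI = (NIR − red)/(NIR + red).
2. **Reliable pixels.** After a class-wise 3×3 boundary erosion, samples of
   ≤ 5,000 focal-class and ≤ 10,000 other-class pixels are clustered on the
   features with a self-organizing map; focal pixels in clusters with
   purity ≥ 0.75 are kept, screened against the class's per-band
   [2.5, 97.5]% intervals, and sub-sampled to 5,000 rows restoring the
   map's class proportions while maximizing intra-class spread (greedy
   max-min selection).
3. **Stratified classification.** One 500-tree probability random forest
   per stratum (mtry = ⌊√12⌋ = 3), predicted over the stratum plus a
   buffer; overlapping stratum memberships are fused by a geometric mean.
   Confidence is the *equivalent reference probability* (ERP): the
   M ∈ [1/n, 1] whose reference distribution (one class at M, the rest
   uniform) has the entropy of the observed vote vector; ERP = max(p) for
   reference-shaped p.
4. **Filtering.** 3×3 majority filtering, conventionally
   (M(s) = argmax_i Σ_j I(h_j = i)) or weighted by within-window-normalized
   ERP (M_w(s) = argmax_i Σ_j ω_j I(h_j = i)), then binarization to
   cropland / non-cropland.

Assessment: confusion-matrix scores (OA ± binomial SE, per-class F-scores),
spatially constrained local accuracy on a regular grid of windows with an
IDW surface, Mann-Whitney confidence separation of correctly vs incorrectly
classified cropland pixels, and tie-corrected Friedman + Nemenyi ranking of
per-stratum feature importances.

A seeded synthetic-scene generator (`generate_scene`, `make_outdated_map`,
`inject_speckle`) reproduces the statistical structure the method assumes —
field mosaics, class-specific NDVI phenology, cloud gaps, label noise and
land-cover change — so the whole pipeline runs and is tested without any
satellite download. See the methods vignette
(`vignettes/cropland-mapping-methods.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(freshmap)

cfg <- scene_config(width = 128, height = 128, n_dates = 24,
                    stratum_count = 2, seed = 42)
scene <- generate_scene(cfg)
outdated <- make_outdated_map(scene$truth, flip_rate = 0.2,
                              change_fraction = 0.05, seed = 43,
                              fields = scene$fields)
mean(outdated$labels == scene$truth$labels)
#> [1] 0.777     # the label source is right for ~78% of pixels only

result <- map_cropland(scene$stack, outdated, strata = scene$strata, seed = 44)
result
#> <cropland_map> 128 x 128, 2 strata, 23.1% cropland

confusion_and_scores(result$binary, binarize(scene$truth))
#> <accuracy_report> n = 16384, OA = 0.9960 (SE 4.95e-04)
#>   FS_cropland = 0.9913, FS_non_cropland = 0.9974

sep <- confidence_separation(result$erp, result$binary, binarize(scene$truth))
sep$p_value; sep$direction
#> [1] 3.75e-20
#> [1] "correct_higher"
```

Although ~22% of the training labels were wrong, the harvested forest maps
cropland at 99.6% binary overall accuracy on this scene, and misclassified
cropland pixels carry significantly lower ERP confidence than correct ones
— the property the weighted majority filter exploits. `result` also holds
the fused memberships, the ERP plane, the per-stratum Gini importances and
the training sets.

A thin command-line front end is installed with the package
(`inst/cli/freshmap`): `freshmap simulate`, `freshmap map`,
`freshmap assess` operate on scene directories of TIFF rasters with JSON
sidecars and GeoJSON polygons.

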