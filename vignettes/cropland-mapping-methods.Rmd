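---
title: "Updating cropland maps from outdated land cover information: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating cropland maps from outdated land cover information: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freshmap)
```

## The problem

Supervised cropland mapping over large territories is usually blocked by the
lack of up-to-date training data. `freshmap` implements a fully automated
alternative: the only label source is an *outdated* land cover map, which
carries two kinds of error — original misclassification and genuine land
cover change since its production. The pipeline extracts the pixels of that
map that are still trustworthy, trains region-specific classifiers on them,
and produces an updated binary cropland map together with a per-pixel
confidence estimate.

The classification scheme has four stages:

1. **Spectral-temporal features.** Each pixel's multi-date reflectance
   series (red, NIR, SWIR1, SWIR2, with a per-observation validity mask) is
   condensed into twelve bands: the per-band median over the valid
   observations, the per-band mean over the observations in the lowest
   decile of the pixel's NDVI values, and the same for the highest decile.
   The NDVI deciles anchor the composites to phenology — for annual crops
   the low-NDVI composite sees bare soil and the high-NDVI composite peak
   canopy — which is what separates cropland from spectrally similar
   grassland.
2. **Reliable pixels.** Per stratum and per class `c`: boundary pixels of
   the outdated map are removed with a class-wise 3×3 (8-connected)
   erosion; a seeded sample of up to 5,000 class-`c` pixels and 10,000
   pixels of the other classes is clustered on the standardized 12-band
   features with a self-organizing map; class-`c` pixels in clusters whose
   class-`c` purity reaches 0.75 are flagged reliable; rows outside the
   empirical \[2.5, 97.5\] percentile interval of their class in any
   feature band are dropped; finally the per-class reliable pools are
   sub-sampled to 5,000 rows that restore the class proportions of the
   (eroded) outdated map, using greedy max-min selection in standardized
   feature space to maximize intra-class spread.
3. **Stratified classification and fusion.** Each stratum gets its own
   500-tree random forest (3 split candidates per node, `floor(sqrt(12))`),
   predicted over the stratum dilated by a buffer so neighbouring stratum
   maps overlap. Overlapping membership vectors (tree-vote fractions) are
   fused by a componentwise geometric mean and renormalized; the hard label
   is the membership argmax. Per-pixel confidence is the *equivalent
   reference probability* (ERP): the value `M` in `[1/n, 1]` such that a
   reference distribution putting `M` on one class and spreading the rest
   uniformly has the same Shannon entropy as the observed vector. ERP uses
   the full probability vector yet equals `max(p)` whenever `p` is itself
   reference-shaped.
4. **Filtering and binarization.** A 3×3 majority filter removes speckle;
   in the weighted variant each window member votes with its ERP,
   normalized within the window, so confident neighbourhoods overrule
   low-confidence speckle even when it is locally in the majority. The
   filtered map is collapsed to cropland (cropland + irrigated cropland)
   versus non-cropland.

Accuracy is assessed globally (overall accuracy with binomial standard
error, per-class user's/producer's accuracy and F-scores), spatially (local
confusion matrices on a regular grid of windows, interpolated by
inverse-distance weighting), by a Mann-Whitney test comparing the ERP of
correctly and incorrectly classified cropland pixels, and feature
importances are compared across strata with a tie-corrected Friedman test
plus Nemenyi critical differences.

## What the synthetic scenes emulate

No satellite data ships with the package; `generate_scene()` produces
seeded scenes carrying the statistical structure the method relies on:

- a mosaic of rectangular fields on a jittered grid (sizes 6–20 px by
  default), creating the boundary-pixel effects that motivate erosion and
  edge-aware validation;
- nine land cover classes with class-specific seasonal NDVI trajectories
  (sinusoid baseline/amplitude/phase per class), from which red and NIR are
  back-computed exactly and the SWIR bands decrease with greenness.
  Cropland swings from a bare-soil minimum (NDVI 0.10, bright red/SWIR) to
  a peak of 0.80; irrigated cropland is phase-shifted with darker SWIR;
  grassland is a moderate 0.25–0.65 swing; forest an evergreen plateau;
  water has negative NDVI and low NIR throughout;
- a class mix dominated by grassland and shrubland with about 20% cropland
  (an extensive-rangeland landscape such as the one the method was designed
  for), i.i.d. Gaussian reflectance noise (sd 0.02 by default), and a
  configurable fraction of cloud-masked observations (0.3 by default);
- degradation of the truth into an "outdated" map via `make_outdated_map()`:
  uniform per-pixel label flips (classification error) and whole-field
  relabeling (spatially coherent change).

The generator does *not* emulate mixed pixels, sensor point-spread,
topographic or atmospheric effects, co-registration error, or intra-class
spectral gradients across a scene. Passing tests therefore show that the
algorithmic chain is correct and behaves as designed under the stated noise
model — not that the accuracy levels reached on synthetic scenes transfer
to real imagery, where class overlap is far stronger.

`inject_speckle()` emulates the error structure of an *unfiltered*
classification for studying the post-filters in isolation: isolated flipped
pixels plus small coherent wrong patches (3×3 by default), with a synthetic
confidence plane in which errors score low (0.15–0.55) and correct pixels
high (0.80–0.98). The low error-confidence range represents split-vote
speckle, whose ERP sits near the `1/n` floor; it is the regime in which
confidence-weighted filtering can correct coherent wrong patches that plain
counting keeps (the interior edge pixels of a 3×3 patch hold a 6-to-3
local majority and survive the unweighted filter).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_valid` (features) | 3 | observations | below 3 the "decile" degenerates to the same single observation as the min/max and the median is fragile; pixels below it are nodata |
| decile membership | `NDVI <= q10` / `>= q90` | — | inclusive empirical (type-7) quantiles guarantee a non-empty composite |
| `n_class` / `n_other` (harvest) | 5,000 / 10,000 | pixels | focal and contrast sample caps per class |
| purity threshold | 0.75 | proportion | minimum cluster purity for reliability |
| SOM grid | ~`5*sqrt(n)` nodes, capped 16×16 | nodes | standard sizing rule; 10 batch iterations, Gaussian neighbourhood with linearly decaying radius |
| `n_total` (training) | 5,000 | rows | target stratum training size; largest-remainder quotas restore class proportions |
| forest | 500 trees, mtry 3 | — | vote fractions are the membership vector; Gini importances retained |
| `buffer_px` | 8 | pixels | stratum overlap for seamless fusion (the real-data analogue is a one-third-degree buffer) |
| fusion floor `eps` | 1e-6 | probability | prevents a single zero vote from annihilating a class in the geometric mean |
| filter window | 3×3 | pixels | single pass; ties keep the centre label; windows truncated at borders |
| ERP bisection | 1e-8 | tolerance | entropy is strictly decreasing in `M`, so bisection is safe |
| local accuracy | `min_count` 500 | pixels | masks windows with too few reference pixels (the real-data defaults are a 40-km grid with 90×90-km windows; in synthetic scenes both are given in pixels) |

## Numerical and design choices

- **Decile convention.** No quantile convention is universal; observation
  `j` is in the first decile iff `NDVI_j <=` the empirical type-7
  0.1-quantile, inclusive of ties. This matches `stats::quantile` and never
  yields an empty composite.
- **Even-length medians** average the central pair.
- **Nodata propagation.** A pixel missing any feature band is wholly nodata
  — classification needs the full 12-vector.
- **95% interval filter** uses per-band empirical percentiles rather than
  `mean ± 1.96 sd`; percentiles are robust to the very outliers the filter
  is meant to remove. Below 20 rows the interval is meaningless and the
  filter passes through with a warning.
- **Max-min sub-sampling** is a greedy farthest-point traversal seeded at
  the row closest to the class centroid; it is deterministic and exhausts
  distinct feature vectors before ever picking a duplicate.
- **Fusion of unequal class sets.** Stratum models can see different class
  sets; memberships are zero-padded onto the union before fusion, and the
  `eps` floor keeps absent classes from annihilating the product.
- **Ties** in the membership argmax go to the lowest class code and are
  counted; ties in both filters keep the centre label (conservative:
  the input survives where the evidence is balanced).
- **ERP degenerate cases.** The uniform vector maps to `1/n`, a one-hot
  vector to 1; `0 log 0` is taken as 0 throughout.
- **Friedman statistic** uses midranks and the tie correction
  `1 - sum(t^3 - t) / (N k (k^2 - 1))`; when every feature ties within
  every stratum the correction vanishes and the statistic is defined as 0.
  The Nemenyi critical difference uses the studentized-range quantile at
  infinite degrees of freedom by default; the `df` argument is exposed
  because post-hoc conventions differ between sources (for k = 12 features
  and N = 9 strata the infinite-df constant gives CD = 5.5545, and other
  df conventions give slightly larger values).
- **Mann-Whitney edge case.** When both confidence groups are one tied
  constant the tie-corrected variance is zero; the midrank convention gives
  p = 1 rather than NaN.
- **Erosion at stratum edges.** Training for a stratum is drawn from the
  stratum core only; masking the outdated map to the stratum before
  erosion also erodes along the stratum boundary, which is intentional
  (those pixels are boundary pixels for the purpose of training).

## Problem sizes used by the tests and the acceptance script

The shipped checks run on scenes chosen to exercise each property at a
scale where its expected effect is much larger than Monte-Carlo noise:
end-to-end mapping on five 256×256 scenes (24 dates, 3 strata, 20% label
flips plus 5% field change); harvesting gain on five 128×128 scenes with
25% flips; filter comparisons on ten 96×96 speckled scenes; ERP and filter
oracles on 1,000 random vectors/windows; Friedman calibration against the
exhaustive 1,296-permutation null at k = 3, N = 4 with 10,000 simulated
data sets. The confidence-separation check uses scenes with elevated noise
(sd 0.04) and cloud cover (0.35) so the resulting maps carry an
ambiguity-driven error population: on nearly error-free maps the test has
no power, and under extreme degradation whole corrupted classes can be
mapped *confidently* wrong, a failure mode of training on a degraded label
source that confidence cannot flag.

## Known limitations

- The SOM is a compact batch implementation (deterministic under a seed);
  it is adequate for purity-based screening but exposes only grid size and
  iteration count.
- The max-min sub-sampling stands in for the dissimilarity-maximizing
  selection of the original workflow, whose exact procedure is not public.
- Class proportions are taken from the eroded outdated map inside the
  stratum, so a class wiped out by erosion contributes no quota.
- Synthetic strata are vertical bands; arbitrary stratum rasters are
  accepted by `map_cropland()` but polygon-based stratification is limited
  to the rectangle GeoJSON writer/reader shipped here.
- On real imagery the accuracy figures of the synthetic checks are upper
  bounds; mixed pixels and co-registration error (both deliberately absent
  from the generator) were the dominant error sources reported for this
  family of methods.
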