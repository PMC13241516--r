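---
title: "Quantifying condensates in extract-in-oil droplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensates in extract-in-oil droplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceodr)
```

## The measurement problem

Cytosolic extract-in-oil droplets (CEODs) are surfactant-stabilised
water-in-oil emulsion droplets encapsulating translation-competent cell
extract. Under stress-mimicking treatments, stress-granule-like biomolecular
condensates assemble inside them, marked by fluorescent G3BP1 fusions. The
quantitative readouts are per-droplet and per-replicate: what percentage of
droplets carry condensates, how much droplet area the condensates cover, and
how large and how irregular the condensates are. `ceodr` implements that
quantification as an open, tested pipeline over two-channel 2-D micrographs:
the *reporter* channel (a spiked reporter filling every droplet) drives
droplet detection; the *marker* channel (e.g. YFP-G3BP1) drives condensate
detection. Imaging is at the droplet equator and all analysis is 2-D; no
z-stacks are modelled.

Because the raw micrographs behind the original measurements are not
available for direct reuse, the package ships a synthetic-scene generator
with full ground truth. The generator is first-class, tested code: every
downstream stage is validated against scenes whose true droplet positions,
condensate masks, and morphology are known exactly.

## The synthetic-scene model

A scene (`scene_config()`) is defined by:

* **Droplet sizes.** Diameters are log-normal with log-mean `diam_log_mu`
  (default 3.2308, i.e. a median of `exp(3.2308)` = 25.3 µm) and log-sd
  `diam_log_sigma` (default 0.45). Only a median and spread are reported for
  real emulsions; log-normal is a stand-in chosen because droplet sizes are
  strictly positive and right-skewed, not a claim about the true
  distribution shape.
* **Placement.** Discs are placed by rejection sampling, fully inside the
  image with a 2 µm rim clearance, largest first. A bounded retry budget
  turns infeasible packings into a "scene too crowded" error naming the
  achieved count. Real emulsions contain touching droplets; the generator
  deliberately does not, because the segmenter flags rather than splits
  touching objects (see Non-goals below).
* **Reporter fill.** Each droplet's fill is
  `intensity_base + intensity_diameter_slope × diameter` plus Gaussian
  jitter (sd 5% of the base). The defaults (6000 a.u. base, 40 a.u./µm
  slope on the 16-bit scale) give fills of roughly 6.5–9 ×10³ a.u. — a mild
  diameter dependence that reproduces the positive correlation between mean
  fluorescence and droplet diameter seen in uniformly loaded droplets, while
  keeping all droplets far above background so a single global threshold
  treats small and large droplets alike.
* **Condensates.** Each droplet is condensate-positive with probability
  `condensate_prob` (default 0.75); positive droplets receive `1 + Poisson`
  condensates. Shapes are radial-perturbation polygons
  `r(θ) = r0 (1 + Σ a_j cos(jθ + φ_j))`, harmonics j = 2…6 with amplitudes
  up to `1/j`, scaled so the polygon arc length matches a target perimeter
  drawn uniformly from `condensate_perimeter_range_um` (default 15–34 µm).
  The amplitude ceiling was set so the analytic circularity of generated
  shapes has its median near 0.6 (quartiles ≈ 0.57–0.70), matching the
  irregular, visibly non-spherical morphology of stress-induced condensates.
  Masks are rasterized strictly inside the parent disc; shapes that cannot
  fit are shrunk, then skipped with a warning.
* **Rendering and noise.** The marker channel carries a dim droplet fill
  (fixed at 10% of the reporter fill) plus condensate pixels at
  `condensate_intensity` (default 30 000 a.u. ≈ 117 on the 8-bit-equivalent
  scale). Both channels receive Poisson-scaled shot noise
  (sd = `sqrt(v · noise_poisson_scale)`) and additive Gaussian read noise
  (sd 120 a.u.) on top of a flat 200 a.u. camera offset, then round and clip
  to 16 bits. Values pushed below zero by noise clip silently at the sensor
  floor; clipping at the 16-bit maximum is reported, as it signals a
  mis-parameterised scene.
* **Determinism.** Each generator stage seeds its own stream from
  `rng_seed` plus a fixed per-stage offset (sampling +0, injection +1,
  rendering +2), so every operation is independently bit-reproducible for a
  fixed seed and `simulate_scene()` is reproducible end to end.

What the generator does **not** emulate: optics beyond pixel-level noise (no
point-spread function; droplet edges are step edges), touching or coalescing
droplets, intra-droplet intensity gradients, out-of-focus light, and
condensate internal texture. Tests passing on synthetic scenes therefore
demonstrate the correctness of the measurement chain, not robustness to
every artefact of real microscopy — on real data the droplet threshold in
particular may need the manual override described below.

## Segmentation

**Droplets** (reporter channel): Gaussian pre-filter (sigma 2 px), intensity
threshold, hole filling, 8-connected labeling, then removal of components
below `droplet_min_area_um2` (default 20 µm²) and, by default, components
touching the border — truncated droplets would bias area fractions and the
diameter distribution. The threshold defaults to Otsu's method rather than a
per-experiment manual setting, for reproducible automation; a fixed
`droplet_threshold` reproduces manual behaviour. Otsu happily bisects even a
pure-noise image, so the automatic mode additionally requires real bimodal
separation (foreground mean at least 4 background-sd above the background
mean, a factor ~10 below what genuine scenes show) and otherwise returns an
empty map.

**Condensates** (marker channel): median-filter denoising (radius 2 px) — an
edge-preserving substitute for proprietary learned denoising — followed by
rolling-ball background subtraction and a fixed threshold of 60 on the
8-bit-equivalent display scale, linearly rescaled (×257) for 16-bit data. A
fixed threshold, not Otsu, keeps conditions comparable: an auto-threshold
would adapt to each image's condensate load and distort between-condition
comparisons. Whether the original acquisition software thresholded before or
after display scaling is not recoverable; the 8-bit-equivalent convention is
this package's declared choice, configurable via `condensate_threshold`.
No hole filling here: condensates may be thin or irregular.

**Rolling ball.** Implemented as the residual of grayscale morphological
opening by a flat disc of `rolling_ball_radius_px` (default 50 px — much
wider than any condensate, narrower than a droplet). The opening uses
EBImage's grayscale erode/dilate, which are exact min/max filters only for
values in [0, 1]; intensities are scaled to unit range before morphology and
back after, which is lossless because min and max commute with monotone
scaling. The result equals a brute-force opening (out-of-image pixels
ignored) to machine precision, and the test suite asserts that equivalence
on random images.

**Mother–child assignment.** Each condensate is attributed to the droplet
under its intensity-unweighted centroid pixel; if that pixel is background
(possible for crescent-shaped children straddling a rim), the droplet with
the largest pixel overlap wins, smallest label on ties; children overlapping
no droplet are orphans (`parent_label = NA`), excluded from per-droplet
statistics and counted separately. One child never maps to two parents.

**Conventions.** 8-connectivity throughout (EBImage's 4-connected labeling
is merged across diagonal adjacencies with a union-find pass); labels are
consecutive from 1 in row-major scan order of each object's first pixel;
pixel (i, j) (1-based in R) has its centre at physical
`x = (j−1)·pixel_size_um`, `y = (i−1)·pixel_size_um`.

## Morphology

Area is pixel count × pixel size². Perimeter uses a chain-code estimator on
the traced object boundary with Kulpa weights (0.948 per axial step, 1.340
per diagonal step). On rasterized discs of radius ≥ 20 px its error is about
−0.5%, well inside the ≤ 2% accuracy contract; naive border-pixel counting
overestimates disc perimeters by ~27% and would make circularities
meaningless. A Crofton 4-direction estimator (`crofton_perimeter()`) is also
provided for cross-checking; it overestimates discs by ~1.6%, which is why
the chain-code estimator is the default inside `measure_objects()`.
Degenerate boundaries (< 4 steps) fall back to the equivalent-circle
perimeter.

Circularity is `4π·area/perimeter²`, clipped at 1 because discretization can
push the raw value of near-circular rasterized shapes slightly above 1.
Note that for condensates only a few pixels across, rasterization plus
median filtering smooths fine boundary structure, so measured circularities
of small irregular objects run higher than their analytic values; circularity
histograms are comparable between conditions but are not unbiased estimates
of continuum shape.

Objects are classed by perimeter: `FOCUS` ≤ 15 µm (the small pre-existing
G3BP1-positive particles seen without stress; the boundary is inclusive),
`CONDENSATE` in (15, 34] µm, `LARGE` beyond. Foci are reported but included
in condensate statistics by default, since no exclusion rule is established
for the replicate-level readouts; `exclude_foci = TRUE` removes them from
the histograms for the alternative reading.

Replicate summaries report percent condensate-positive droplets (a missing
value, not 0, when there are no droplets), the median across pooled droplets
*and* mean ± SD of the condensate-area fraction — both views are standard —
and perimeter/circularity frequency histograms with left-closed right-open
bins (last bin closed). Values outside the supplied bin edges are counted in
the first/last bin so histogram counts always conserve the number of
objects.

## FRAP recovery

Traces are normalized frame-by-frame to a non-bleached reference region of
the same droplet or extract (cancelling illumination drift) and scaled so
the pre-bleach mean is 100%. Recovery is fitted by least squares to the
minimal single-exponential model `I(t) = P − (P − I0)·exp(−kt)` with t
re-zeroed at the first post-bleach frame; bleach-duration frames are simply
not part of the trace. Initialization is deterministic from the data
(I0 = first post-bleach value, P = mean of the last 10% of frames,
k = ln 2 over the time to half range), and the optimizer
(`minpack.lm::nlsLM`) runs with k bounded in [10⁻⁸, 10⁴] s⁻¹; a fit at a
bound is flagged. The reported half-time is `t½ = ln 2 / k`; the mobile
fraction `(P − I0)/(100 − I0)` is reported but is a secondary quantity. No
photobleaching-decay correction is applied beyond reference normalization,
and no diffusion-coupled (Soumpasis) or double-exponential models are
offered: the half-time of the minimal model is the quantity of record.
On noiseless synthetic traces the fit recovers rate constants to numerical
precision; at 2% noise, 0.5 s sampling and 180 s duration the median
relative error of k is well under 5%.

## Overlap and colocalisation statistics

`pearson_line_profile()` is the sample Pearson R between two channel
intensity series along a drawn line; constant channels are an error, not a
silent 0 or 1. `hypergeom_overlap()` is the upper-tail (enrichment-only)
hypergeometric test, evaluated on the log scale so gene-scale universes do
not underflow, with the enrichment factor `k/(nK/N)`. The universe is never
defaulted silently: `overlap_test()` requires an explicit identifier
universe, because the test's significance is an artefact of whatever
universe is assumed. `bh_adjust()` is the standard Benjamini–Hochberg
step-up. These lean on R's `phyper` and `p.adjust`; the test suite verifies
them against exhaustive draw enumeration (all universes up to N = 12) and a
hand-applied step-up rule, respectively.

## Problem sizes and the reproduction script

The cohort-scale checks simulate 8 scenes of 125 droplets (1000 droplets) in
the test suite and 16 scenes (2000 droplets) in
`scripts/acceptance.R` — enough that the sampling error of the median
diameter is a fraction of a percent while a full run stays under a minute on
one CPU. At these sizes the detected median equivalent diameter lands within
about 1% of the generator's 25.3 µm target, ground-truth condensates are
recovered at ≥ 95% with ≥ 50% pixel overlap, and detected condensate-area
fractions track truth with Spearman ρ > 0.99.

## Known limitations

* Touching droplets are not split (no watershed); the generator never
  produces them, and on real images they would be merged into one label —
  use the border/area filters and visual inspection.
* The droplet threshold's automatic mode assumes a clearly bimodal
  reporter histogram; dim or unevenly loaded droplets call for a manual
  threshold.
* Perimeters of objects only a few pixels across are estimator-limited;
  between-condition comparisons are sound, absolute values carry a few
  percent of bias.
* FRAP fitting assumes a single kinetic population; traces with two
  well-separated timescales will fit poorly (inspect `autoplot()` of the
  fit and the residual sum of squares).
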