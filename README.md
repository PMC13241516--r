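# ceodr

Quantification of stress-granule-like biomolecular condensates inside
cytosolic extract-in-oil droplets (CEODs) from two-channel fluorescence
micrographs. CEODs are surfactant-stabilised water-in-oil emulsion droplets
encapsulating translation-competent cell extract; under stress-mimicking
treatments, condensates marked by fluorescent G3BP1 assemble inside them.
`ceodr` is for researchers who need the standard readouts of such
experiments — per-droplet condensate load, morphology distributions, FRAP
mobility, and light colocalisation/overlap statistics — as an open, tested,
scriptable pipeline rather than a point-and-click workflow.

The package provides:

* **A synthetic micrograph generator with ground truth** (`scene_config()`,
  `simulate_scene()`, `export_scene()`): circular droplets with log-normal
  diameters (median `exp(µ_log)`, default 25.3 µm), diameter-correlated
  reporter fill, irregular star-shaped condensates with target perimeters of
  15–34 µm, Poisson + Gaussian camera noise, and single-exponential FRAP
  traces (`simulate_frap_trace()`). Every downstream stage is testable
  against exact ground truth.
* **Two-channel segmentation** (`segment_droplets()`,
  `segment_condensates()`, `assign_condensates()`): Gaussian pre-filter and
  Otsu (or manual) threshold for droplets; median denoising, rolling-ball
  background subtraction (grayscale opening residual,
  `subtract_background_rolling_ball()`) and a fixed 8-bit-equivalent
  threshold of 60 for condensates; mother–child assignment by centroid with
  largest-overlap fallback.
* **Morphology and aggregation** (`measure_objects()`,
  `summarize_droplets()`, `summarize_replicate()`): area, sub-2%-accurate
  chain-code perimeter, circularity `4π·area/perimeter²` (1 = perfect
  circle), perimeter classes (focus ≤ 15 µm < condensate ≤ 34 µm < large),
  condensate-area fraction per droplet, percent condensate-positive
  droplets, and frequency histograms.
* **FRAP fitting** (`normalize_trace()`, `fit_recovery()`): reference
  normalization to percent of pre-bleach, least-squares fit of
  `I(t) = P − (P − I0)·e^(−kt)`, half-time `t½ = ln2/k`, mobile fraction;
  `tidy()`/`glance()`/`autoplot()` methods included.
* **Statistics** (`pearson_line_profile()`, `hypergeom_overlap()`,
  `overlap_test()`, `bh_adjust()`): line-profile Pearson colocalisation and
  upper-tail hypergeometric set-overlap enrichment with Benjamini–Hochberg
  FDR adjustment.

All tabular inputs and outputs are tibbles, so analyses compose with the
pipe; `run_quantify()` orchestrates the full chain and writes a
reproducible report bundle (CSV tables, label-map TIFFs, summary JSON, run
manifest).

## Worked example

Simulate a 120-droplet scene, quantify it, and fit a FRAP trace:

```r
library(ceodr)

cfg <- scene_config(n_droplets = 120, rng_seed = 42)
sc  <- simulate_scene(cfg)

dm <- segment_droplets(sc$channels$reporter)
cm <- segment_condensates(sc$channels$marker)
pa <- assign_condensates(dm, cm)
dr <- measure_objects(dm, sc$channels$reporter)
cr <- measure_objects(cm, sc$channels$marker)
ds <- summarize_droplets(dr, cr, pa)
summarize_replicate(ds, cr)
#> <replicate_summary> 120 droplets, 107 condensates; 71.7% positive;
#>   area fraction median 3.40%, mean 5.94% +/- 7.66%
```

All 120 simulated droplets are detected; 71.7% of them contain at least one
condensate (the generator's condensate probability is 0.75), and the median
droplet devotes 3.4% of its cross-sectional area to condensate — the
replicate-level numbers a treatment comparison would be built on.

```r
tr  <- simulate_frap_trace(log(2) / 4.8, noise_sd = 1.8, seed = 7)
fit <- fit_recovery(normalize_trace(tr))
fit
#> <frap_fit> k = 0.1464 1/s, t1/2 = 4.73 s, plateau = 90.3%,
#>   mobile fraction = 0.88 (RSS 1.16e+03, n = 361)
```

A trace generated with a 4.8 s half-time and 2% noise fits back to
t½ = 4.73 s with an 88% mobile fraction: fast G3BP1 exchange typical of
liquid-like condensates.

See `vignettes/condensate-quantification.Rmd` for the full account of the
models, parameter choices, and limitations.

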