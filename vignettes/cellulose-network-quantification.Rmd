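---
title: "Quantifying regenerating cellulose networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regenerating cellulose networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwrq)
```

## The measurement problem

Plant protoplasts regenerate a primary cell wall in culture; the nascent
cellulose network can be stained (Calcofluor for beta-glucans, CBM3a
immunolabel for crystalline cellulose) and imaged as confocal z-stacks of
the cell surface. The biological questions — does a genotype or treatment
change how much network is made, and how bundled its fibrils are — are
answered with four per-cell numbers computed from a skeletonised
maximum-intensity projection:

* **Total length** — the skeleton pixel count `N_cellulose` converted to
  millimetres by the lateral calibration. It is a pure count times pixel
  size: no diagonal-step correction is applied, so the value is the
  apparent network length at the image's sampling. Digitisation makes the
  count a biased estimator of true arc length (an 8-connected chain
  under-counts diagonal runs by up to 29%, while staircase wiggle in a
  thinned noisy skeleton over-counts), but the bias is common to all cells
  imaged under the same settings, and the endpoint is always a
  between-group comparison.
* **Mean intensity** — the arithmetic mean of the *source-image* intensity
  over skeleton pixels, in native acquisition units.
* **CV** — the population standard deviation of those intensities divided
  by their mean.
* **Skewness** — the third standardised population moment,
  `S = mean(((i - mean(i)) / sigma)^3)`.

CV and skewness are the bundling metrics: when fibrils aggregate
laterally, the same fluorophore concentrates into fewer, brighter lines,
stretching the intensity distribution to the high side. Both moments use
the population (1/N) convention, exactly as the endpoint formulas are
written — not the sample-corrected (N−1) estimators.

Coordinates are 1-based (row, col) with the pixel-centre convention, R's
native indexing; serialised skeletons record `index_base = 1`.

## Skeleton extraction

The curvilinear extractor follows the classical Hessian-ridge
(Steger-style) design, with the parameter vocabulary of spur shaving and
short-component deletion used for these images
(`giws_iter = 2`, `mdnms_len = 3`, `pickup = "above"`, `shave_len = 5`,
`del_len = 5`):

1. `giws_iter` rounds of Gaussian smoothing at scale `ridge_sigma_px`
   (default 1.5 px; the effective detection scale after two rounds is
   ~2.1 px, appropriate for fibril images whose rendered line width plus
   point-spread function is 3–4 px).
2. Hessian ridge response: the negative minimum eigenvalue of the local
   Hessian, kept signed (positive on bright ridges, negative on flanks),
   damped by an anisotropy factor `1 - (lambda1/lambda2)^2` on the
   positive side so isotropic blobs (dot-like artifacts, fiber end caps)
   do not masquerade as short ridges.
3. The response is pooled along the ridge tangent over `mdnms_len` pixels
   — averaging along the line damps shot-noise fluctuations without
   blurring across lines — and non-maxima across the ridge normal are
   suppressed.
4. `pickup = "above"`: pixels whose pooled response exceeds an automatic
   threshold are kept. The threshold is `bg_location + k * bg_scale` with
   `threshold_k = 3.5` by default. The background statistics are
   **noise-referenced**: the image noise sd is estimated robustly from
   in-mask horizontal pixel differences (median absolute difference), a
   matched white-noise field is pushed through the identical response
   operator (with a fixed internal seed, so extraction stays
   deterministic), and the median/MAD of its in-mask response give the
   background location and scale. Statistics of the observed response
   would be contaminated by the signal tail and would rise with network
   density, silently dropping dim fibers in dense cells; the
   noise-referenced calibration is density-independent. `k = 3.5` places
   the cut at a point where, over the tens of thousands of background
   pixels in a typical field, essentially no shot-noise ridges survive
   (a 2-sigma cut would admit ~2% of them). For an essentially
   noise-free image the estimator falls back to robust statistics of the
   observed response itself.
5. Background holes smaller than 9 px are filled (genuine network pores
   are far larger), then the map is thinned to one pixel with Zhang–Suen
   thinning using a fixed raster-order pass schedule, plus a final
   cleanup that removes deletable pixels from any remaining 2×2 blocks
   (deletable = the set neighbours form a single 8-connected component).
6. Terminal branches shorter than `shave_len` px — the path from an
   endpoint up to and including the pixel that attaches to the main body
   — are removed iteratively to a fixed point; then 8-connected
   components smaller than `del_len` px are deleted. 8-connectivity is
   used throughout.

Intensities are sampled from the original, unsmoothed image: the
endpoints are statistics of the stain's intensity distribution, not of a
filtered image. Masked-out pixels (background, bright callose-like dots)
never enter the threshold statistics, the skeleton, or the intensity
sample; masks flag pixels rather than zeroing them, because zeroed values
would corrupt the intensity distribution, and compose by intersection.

## The synthetic scene generator

No raw imaging data accompany the measurements this package implements,
so every stage is validated against synthetic scenes with known ground
truth. A confocal-like scene is a disc-shaped cell projection (default
radius 110 px at 0.124 µm/px — a protoplast of ~14 µm radius under a
×100/NA 1.30 objective, 256×256 px field) carrying `n_fibers` fibers of
~15 µm arc length, drawn as bounded-curvature random walks (step 4 px,
heading increments N(0, 0.25 rad)) reflected at the disc boundary.

Bundling is modelled structurally: fibers are grouped into bundles of
`bundling_factor` that share one backbone with sub-pixel lateral jitter
(< 0.35 × fiber width). Each fiber carries the same expected photons per
unit length (default 600), so increasing the bundling factor at fixed
fiber count concentrates the same total fluorophore into fewer, brighter
lines — making "same fluorophore, fewer brighter fibers" literally true,
which is the premise behind CV and skewness as bundling metrics. Two
ground-truth lengths are recorded: per-fiber (total fluorophore) and
per-backbone (apparent length, what any image-based measurement can see).

Rendering rasterises each fiber by bilinear splatting of line mass,
spreads it across the fiber width with a normalised disc kernel (so total
fluorophore is conserved exactly), adds optional bright disc artifacts,
convolves with a Gaussian PSF (default sigma 1 px), adds uniform
background (default 50 counts), and applies Poisson shot noise plus
Gaussian read noise (default sd 3) before clipping to the sensor range
(default 16-bit). Scenes are 2-D: the maximum-intensity projection is
simulated directly, since the analysis operates on projections, not
volumes. Everything is deterministic given the config's seed.

What the generator does **not** emulate: membrane curvature and the
z-falloff of a real stack, spatially varying background, stain
penetration gradients, and the immunolabel dot patterns of real
double-stained images. Passing the synthetic validations therefore shows
the pipeline measures what it claims on images with this noise and
geometry model, not that any specific biological result is reproduced.

### Validation experiments run by the test suite and acceptance script

* **Length recovery.** Thirty scenes spanning 5–40 fibers at the default
  SNR; the skeleton-length to true-apparent-length ratio averages
  0.88–1.03 depending on the seed set, with mean absolute per-scene
  error of 10–15%. Dense
  scenes lose a little apparent length where parallel fibers approach
  within the PSF scale and genuinely merge; sparse scenes over-count
  slightly through staircase digitisation. Rotating a scene by 90°
  changes the measured length by well under 5%.
* **Bundling response.** With 16 fibers and fixed total fluorophore,
  median CV increases strictly and substantially across bundling factors
  1, 2, 4, 8 (30 scenes per level), while skewness responds erratically
  (it falls, because brighter skeletons sit further above the additive
  background floor, compressing the relative right tail). CV's relative
  change from b = 1 to b = 8 far exceeds skewness's — the basis for
  preferring CV as the bundling metric.
* **Intensity–skewness coupling.** Forty scenes whose per-fiber staining
  brightness spans 150–6000 photons per pixel of arc length (log-spaced —
  cell-to-cell stain loading varies over orders of magnitude) under a
  12-bit detector, the realistic acquisition setting in which the gain
  is set so the brightest cells approach saturation. Mean skeleton
  intensity then anticorrelates with skewness more strongly than with
  CV: at the dim end the background floor compresses the left tail
  (raising skewness), at the bright end ceiling clipping removes the
  right tail (driving skewness negative), and the third moment is far
  more sensitive to both compressions than the second. This reproduces,
  mechanistically, why a slight between-group skewness difference can be
  an intensity artifact while CV differences are not.

## Fiber diameters from high-resolution images

SEM-like scenes render ribbons whose rasterised full width equals the
drawn diameter, sampled from a Gaussian mixture whose default puts the
mode in the 20–30 nm bin. The default frame is 640×640 px at 2 nm/px
(a ~1.3 µm field, matching high-magnification imaging with a 500 nm
scale bar) with 40 fibers; fiber placement rejects centrelines that
mostly run on top of already-placed ribbons, because the scene exists to
validate width measurement and each drawn diameter must remain
individually measurable.

The estimator binarises with Otsu's threshold, thins to a skeleton, and
excludes pixels within 2 px of skeleton junctions (width is ill-defined
where bundles branch). At each sampled centreline pixel the diameter is
measured with a **subpixel caliper**: the gray profile, normalised to
[0, 1] coverage between the background and foreground levels, is
interpolated along the continuous ridge normal (taken from the principal
axis of nearby skeleton pixels — the intensity Hessian carries no signal
inside wide flat-top ribbons), and the diameter is the distance between
the half-maximum crossings on either side. Because anti-aliased edges
carry the subpixel position of the true edge in their gray values, this
measurement is exact for straight ribbons regardless of how the ribbon
falls on the pixel grid. A plain `2 × EDT` (distance-transform) reading
was evaluated first and rejected: it quantises width to whole pixels
with an even/odd parity wobble of ±0.5 px, which at 10-nm histogram bins
misassigns fibers near bin edges. The distance transform is retained to
bound the caliper's search range, and as the fallback where overlap
prevents a half-maximum crossing from being found.

Histograms use left-closed bins of 10 nm from 0. On the default mixture
the modal estimated bin matches the modal true bin in ≥95% of seeded
scenes at n = 500 samples.

## Rupture counts and group comparisons

Osmotic stability is the ratio N30/N0 of intact protoplasts after versus
before an osmotic downshift; the simulator draws
N30 ~ Binomial(N0, p_survive). Ratios slightly above 1 are legal (the
two counts come from different aliquots) and produce a warning, not an
error.

The group tests mirror how these endpoints are compared:

* **Mann–Whitney** (two-sided) with midrank U; exact p by enumeration of
  all label assignments when the pooled sample is tie-free and
  n ≤ 12, otherwise the normal approximation with tie and continuity
  corrections. The exact convention is `2·min(P(U ≤ u), P(U ≥ u))`,
  capped at 1.
* **Tukey–Kramer** all-pairs comparison with pooled within-group variance
  and the unequal-n standard error; p-values from the studentized-range
  distribution. With two groups this reduces (q = t√2) to the pooled
  t-test. A compact letter display is built from the maximal cliques of
  the non-significance graph, ordered by group mean.
* **Student's t**, classical equal-variance two-sample form.
* **Pearson correlation** with typed errors on degenerate input.

Stars follow the caption convention: `**` for p < 0.01, `*` for
0.01 ≤ p < 0.05. All tests are two-sided. Replicates are pooled, not
modelled hierarchically, matching how the endpoints are reported.

## Numerical and engineering choices

* Population moments throughout the feature module; undefined features
  (empty skeleton, zero mean, zero spread) raise typed conditions at the
  single-cell level but become flagged `NA` rows in `feature_table()`,
  so batch runs never abort on one degenerate cell.
* All randomness flows through per-config seeds; re-running any
  generator, the extractor, or a CLI command with the same inputs gives
  byte-identical outputs. The extractor's internal noise-reference field
  uses a fixed constant seed and restores the caller's RNG state.
* Images are written as 16-bit grayscale TIFF (integer counts
  round-trip exactly), masks as 8-bit PNG with 255 = keep, skeletons and
  scene ground truth as JSON at full precision.
* Problem sizes in the validation suite (30 scenes per length/bundling
  level, 40 scenes for the coupling experiment, 100 SEM scenes, 2000
  null replicates for test calibration) were chosen as the smallest
  designs whose pass/fail decisions are stable across seeds.

## Known limitations

* The skeleton-count length measure inherits digitisation bias (±10%
  scale-level effects); it is a comparative, not absolute, measure.
* At high network density the extractor cannot separate parallel fibers
  closer than the PSF scale; apparent length saturates accordingly.
* The caliper diameter estimator assumes locally straight, locally
  isolated ribbons; heavily overlapping mats fall back to the
  distance-transform bound and lose subpixel accuracy.
* The line extractor is a faithful re-implementation of the *measurement
  idea* (ridge detection, directional NMS, above-threshold pickup,
  shave/delete pruning), not a bit-identical replication of any existing
  plugin.
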