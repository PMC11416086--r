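---
title: "Methods: droplet extraction and deposition metrics on water-sensitive paper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet extraction and deposition metrics on water-sensitive paper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wspray)
```

## The measurement problem

Water-sensitive paper turns from yellow to dark blue where aqueous spray
droplets land. Scanning a card and segmenting the stains gives two
deposition statistics: coverage (the stained percentage of the card) and
density (stains per unit area). Both depend entirely on how well stain
pixels are separated from paper pixels, and two scan artifacts work against
that: sensor noise, and glare on wet stains that reads as bright holes
inside droplet contours, deflating coverage and fragmenting stains.

`wspray` implements the full chain — grayscale conversion, global
thresholding (three methods), morphological repair, connected-component
counting, metric computation, group classification — plus a synthetic card
generator with exact ground truth, so that every stage is testable.

## Segmentation model

All segmentation operates on an 8-bit gray image. For RGB scans the
default working channel is **red**: WSP paper is yellow (red channel
bright) and stains are blue (red channel dark), so red maximises contrast.
Luma (BT.601) and the other channels remain selectable; the choice is
exposed because scanners and card batches vary.

A pixel is droplet foreground when `f(x, y) < T`. The three thresholds:

* **Fixed**: `T = round(0.60 × 255) = 153`, the conventional constant for
  WSP's strong paper/stain contrast. Cheap, but blind to exposure shifts.
* **Otsu**: `T` maximises the between-class variance
  `sigma^2(k) = (m_G P1 - m)^2 / (P1 P2)` with class 1 the levels
  `[0, k]` and class 2 the levels `[k+1, 255]` (`P1`, `m` the class-1
  probability and cumulative mean, `m_G` the global mean). Splits with an
  empty class define `sigma^2 = 0` so they can never win. The argmax is
  computed from 256-term cumulative sums in double precision, never by
  per-pixel passes per candidate.
* **Genetic-Otsu**: a genetic algorithm searching the same objective
  (below).

Between two separated histogram modes the objective is constant over all
thresholds in the empty gap, so the argmax is a plateau. Both Otsu-type
methods report the **floor of the mean of the maximising plateau**,
centring the threshold between the modes. This tie rule matters: the
plateau's lower edge can equal the stain gray level itself, and with the
`f < T` rule that threshold would classify every stain pixel as
background.

## The genetic search

The GA evolves 8-bit chromosomes decoding to thresholds, with
`sigma^2(k)` as fitness. Defaults (all exposed in `ga_config()`, all
requiring an explicit seed): population 30, 60 generations, single-point
crossover with probability 0.8, per-bit mutation 0.02, tournament
selection of size 3, 2 elites, early stop after 15 generations without
best-fitness improvement. On a 256-point space these settings give
reliable convergence; elitism makes the per-generation best fitness
monotone, which is asserted on every run via the returned trace.

Two design points deserve explanation:

* **Gray-coded chromosomes.** With plain binary encoding, adjacent
  thresholds can differ in many bits (127 and 128 differ in all eight — a
  Hamming cliff), so once the population has converged near a flat-topped
  optimum the ±1 refinement step is practically unreachable by mutation
  before the early stop triggers. Measured over 300 random bimodal
  histograms at default settings, plain binary missed the exact exhaustive
  maximum in 13/300 runs; reflected Gray code, in which every adjacent
  threshold is one bit flip away, missed in 1/300. The package therefore
  decodes chromosomes as reflected Gray code.
* **Plateau canonicalisation.** The GA returns the centre (floor of mean)
  of the contiguous equal-fitness plateau containing its best threshold,
  the same rule as the exhaustive search. This changes neither the
  attained `sigma^2` nor determinism; it only makes the two methods'
  reported thresholds comparable and keeps the `f < T` rule safe at
  plateau edges. During evolution, ranking ties are still broken toward
  the lower threshold, which keeps selection deterministic.

Because the fitness is *exactly* the Otsu criterion, a converged GA and
the exhaustive search coincide; this package makes no claim that the
genetic variant is more accurate than exhaustive Otsu on the same
histogram, and the test suite asserts their equivalence (the GA attains
the exhaustive maximum in ≥ 95% of seeded runs and is always within 0.5%
of it). The genetic search is valuable as a drop-in optimiser when the
objective is evaluated on large images or embedded in larger pipelines;
on a bare 256-bin histogram the exhaustive scan is, of course, cheaper.

## Morphological repair and counting

Glare holes are repaired by **closing** (dilation then erosion) with a
flat structuring element, default a radius-1 disk, meaning the full 3×3
neighbourhood (disks use the rounded rule `dx² + dy² ≤ (r + 0.5)²`). The
closing is computed on a padded canvas, so it is extensive and idempotent
everywhere including at borders; both properties are property-tested on
random masks. The element is configurable because glare-hole size scales
with scan resolution.

Droplets are counted as connected components, default 8-connectivity
(stains are compact blobs; 4-connectivity would split thin diagonal
boundaries and is selectable). Components below `min_droplet_area_px`
(default 2 px) are treated as specks and removed. Coverage is computed
**after** closing and size filtering — the holes are scan artifacts, not
true background, and leaving them would bias coverage low.

### Units

Coverage is a percentage of the card raster. Density is reported as
droplets per cm², using the scan DPI to convert the raster to physical
area (25.4/DPI mm per pixel). The conventional density formula carries a
"× 100%" factor; a percentage of a count is not dimensionally meaningful,
so the package reports the plain count rate and keeps the raw count in
every report. The PA classification uses the printed interval edges
(12,000 and 40,000); values at or above 90,000 fall outside every defined
interval and are classified dense with a warning rather than an error, so
batch runs never abort.

## The synthetic world

`generate_wsp()` renders what the pipeline assumes about a WSP scan:

* light paper at mean gray 210, dark stains at mean 60, Gaussian sensor
  noise with sigma 5 — the default contrast of a clean 96 DPI scan;
* stains are rotated ellipses with log-normal radii (meanlog log(2.5),
  sdlog 0.45 at 96 DPI; deposit size spectra are right-skewed) and axis
  ratios in [1, 1.5];
* 30% of stains carry one glare hole, a strict disc of radius 1 px
  (a 5-pixel plus), restored to paper gray strictly inside the stain;
* the default canvas is 287 × 98 px, a 76 × 26 mm card at 96 DPI.

Ground truth (mask, count, coverage, per-droplet geometry) is fixed
**before** glare and noise, by integer pixel counting with no
anti-aliasing: the truth is exact, at some cost in edge realism. Two
generator choices make exact recovery well-posed rather than accidental:
stamped ellipses are morphologically regularised (closed with the default
3×3 element at render time), so the pipeline's closing step cannot add
boundary pixels; and stains are placed with a minimum Chebyshev gap
(default 3 px), so closing cannot bridge neighbours. Placement is
rejection sampling, bounded at 10,000 attempts per droplet; a crowded
canvas places fewer droplets with a warning, and a spec whose expected
stain demand exceeds the canvas errors immediately.

`generate_group_panel()` draws images whose realised truth PA falls in a
group's interval, steering the droplet count toward a target PA and
redrawing until the interval is hit (bounded at 1,000 draws). A 287 × 98
canvas has only 28,126 pixels in total, so the medium and dense intervals
(PA up to 90,000) are unreachable at the card's nominal 96 DPI; denser
panels therefore use the same card at higher scan resolution (medium
766 × 262 px at 256 DPI, dense 1149 × 393 px at 384 DPI), keeping target
coverage realistic (roughly 7–20%).

### What a green test establishes — and what it does not

With modes at 60 and 210 and noise sigma 5, the Otsu threshold sits about
15 standard deviations from either mode, so no noise pixel ever crosses
it: on this world the pipeline recovers truth *exactly*, and the measured
mean relative errors on sparse panels are at or near zero — comfortably
inside the published sparse-group error bounds (1.5% coverage, 2.7%
density) that the acceptance tests use as upper limits. That validates
the mechanics (thresholding, repair, counting, unit conversion), not
field performance: real scans have intermediate edge pixels from optical
blur and dye bleed, uneven card colour, touching stains, and glare holes
of varying size. None of these are in the generator's default world, and
error rates on real cards will be larger.

## Numerical and interface choices

* Histograms carry integer counts alongside probabilities, so empty-class
  detection in the Otsu criterion is exact rather than
  floating-point-fragile.
* Degenerate histograms (fewer than two occupied levels) raise an error
  from both Otsu-type methods; a uniform image has no meaningful
  threshold.
* All stochastic paths (GA, generator, panels) require explicit integer
  seeds; there is no wall-clock fallback, and the RNG state of the caller
  is restored afterwards.
* Images: PNG and JPEG are read via the `png`/`jpeg` packages, plain
  PGM/PPM via a built-in reader (handy for text fixtures); TIFF is not
  supported (no decoder available) and fails with a clear message.
  Missing resolution metadata falls back to an override argument, then to
  96 DPI with a warning. Note PNG stores resolution as pixels per metre,
  so a nominal 96 DPI reads back as 95.9866.
* Masks serialise to PNG with droplet = 255, the inverse of the raw
  thresholding rule's bright-background convention; documented on
  `write_mask_png()`.

## Known limitations

* Global thresholding only: no local/adaptive thresholds and no
  multi-level Otsu; cards with strong illumination gradients will suffer.
* Touching stains are counted as one droplet; there is no watershed
  splitting, and no droplet-diameter spectrum estimation.
* The relative-error benchmark treats the reference as exact and averages
  unsigned per-image errors per (method, group); significance testing is
  deliberately left to standard statistics tools on the exported CSV.
* The synthetic generator is grayscale; colour rendering and physically
  based droplet spreading are out of scope.
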