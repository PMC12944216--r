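---
title: "Methods: segmentation and wave metrics for protonemal calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and wave metrics for protonemal calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosswave)
```

## The problem

Widefield timelapse imaging of moss protonemal colonies expressing a
genetically encoded calcium indicator (GCaMP) produces stacks of thousands of
frames in which calcium waves rise and fall across filamentous chains of
chloronemal (CH) and caulonemal (CA) cells. Manual region-of-interest (ROI)
annotation is slow and biased, and cell-average traces obscure subcellular
dynamics such as the fast oscillations of the caulonemal apical tip (CA*).
`mosswave` implements an unbiased alternative: every colony pixel is treated
as a time series, and pixels are grouped into contiguous ROIs purely by the
similarity of their fluorescence dynamics. Downstream, each ROI trace is
scanned for calcium waves whose shape, timing, synchrony and entrainment to a
stimulus protocol are quantified.

## Pipeline model and assumptions

The pipeline runs in four stages, each standalone and connected only by
declared file formats (TIFF, CSV, JSON):

1. **Foreground masking.** The stack is flattened by maximum z-projection so
   that any region active at some point appears bright. A rolling-ball
   opening (ball radius 25 px by default, 72 µm at 2.9 µm/pixel; up to 90 px
   for large colonies) estimates and removes smooth background, a disk median
   filter (radius 2.5 px = 7.2 µm) suppresses shot noise, and the triangle
   method picks the threshold automatically from a 256-bin histogram.
   Components smaller than 200 px² (~1600 µm²) are removed. The published
   protocol this follows also removes components by a circularity cut of 0.9;
   because filaments themselves have very low circularity, the rule is
   ambiguous (keep round components, or drop round specks?). The default mode
   `exclude_round` drops only components that are both round *and* small
   (below `speck_cap_px2`), which preserves filaments under either reading;
   `include_round` and `off` are available, and the provenance records the
   mode used.

2. **Correction and normalization.** Each frame is deconvolved by
   Richardson–Lucy iteration (10 iterations) against a Gaussian PSF whose
   FWHM is the Abbe limit 0.61·λ/NA; with GCaMP emission λ = 0.51 µm and a
   0.28 NA objective this is 1.1 µm, deliberately sub-pixel at 2.9 µm/pixel.
   Frame borders are tapered toward their smoothed version over a band two
   PSF widths wide before iterating, which suppresses edge ringing. A
   per-frame background field — the grayscale disk opening (radius 15 px) of
   the frame with colony pixels blanked — is subtracted and negatives are
   clipped. Because fluorescence is brightest at cell centers and dimmest at
   borders, each pixel is then Z-scored over time, `Z = (x − µ)/σ`, which
   makes pixels comparable regardless of their time-averaged intensity. The
   SD uses the sample convention (n − 1); at thousands of frames the
   difference from the population convention is negligible, but one
   convention must be fixed for reproducibility. Pixels with zero temporal
   SD map to all-zero Z-traces rather than NaN, so the matrix stays dense;
   such pixels join a flat cluster and are pruned downstream.

3. **Segmentation.** Foreground pixels form a pixels × time matrix of
   Z-scores. The initial cluster count is the colony area divided by a
   desired mean ROI area of 150 px² (1260 µm², roughly the scale at which
   real cells resolve into 1–3 ROIs), floored and clamped to ≥ 1. k-means
   under the cosine distance (1 − cosine similarity) groups pixels by the
   *shape* of their dynamics, ignoring amplitude; ten random initializations
   are run and the best kept, each followed by an online refinement phase
   that moves single pixels (comparing against their own centroid computed
   without them) whenever the move lowers the total within-cluster distance.
   Because clustering ignores space, each cluster is split into its
   8-connected components (8-connectivity so thin diagonal filaments do not
   fragment), and components below 12 px (101 µm²) are returned to
   background. This split-and-prune step dominates the final ROI count,
   which is why the result is insensitive to the initial k (changing k by
   ±50% moves the filtered count by well under 10% on synthetic colonies).
   Empty clusters are dropped rather than reseeded for the same reason.
   Labels are renumbered by the raster order of ROI centroids so output is
   reproducible. ROI traces are the per-frame mean of background-subtracted
   fluorescence over the ROI's pixels; the baseline F0 is a robust minimum
   (1st percentile by default; 0 gives the strict minimum) and traces are
   reported as ΔF/F0. ROIs whose best response within 5 min of the first
   stimulus onset stays below 100% ΔF/F0 are excluded as non-responsive
   (typical evoked responses reach ~250%).

4. **Wave metrics.** Waves are local maxima whose topographic prominence
   (height above the higher flanking minimum, walking out to the nearest
   higher terrain or the boundary) reaches 0.35 × MAD of the trace. The MAD
   is unscaled — `median(|x − median(x)|)` with no 1.4826 factor — computed
   on the full trace. A pure MAD threshold cannot reject ripples on a trace
   that contains *only* noise, so an absolute floor of 0.25 ΔF/F0 is
   applied: on the smallest admissible ROIs (12 px) at typical camera noise
   the largest ΔF/F0 noise excursions reach ~0.17 over an hour-long trace,
   while the weakest real waves sit near 0.7, so the floor separates the
   two populations with margin on both sides; peaks closer than 10 s
   (far below the ~59 s shortest observed interval) are merged keeping the
   higher. Wave shape is measured at fractions of prominence above the
   peak's base: onset and end are the 10% crossings (linear interpolation),
   FW10 is their span, and rise/fall are the 10%→90% spans per flank. For a
   Gaussian wave of scale σ these have closed forms, FW10 = 4.29193 σ and
   rise = fall = 1.68692 σ, which the tests verify to within one frame
   interval. Waves truncated by the recording boundary are flagged.
   Intervals are peak-to-peak between consecutive same-ROI waves (the
   onset-to-onset alternative is not distinguishable in the source
   protocol); frequency is 60/mean-interval per minute and the CV is the
   sample SD over the mean. The instantaneous wave probability at time t is
   the fraction of ROIs whose FW10 span covers t. Synchrony is the maximum
   over lags (±120 s by default, about two wave durations) of the Pearson
   correlation between mean-centered traces, with fixed full-trace
   normalization so lag 0 equals the ordinary correlation; zero-variance
   traces yield NA, never silent zeros. Per-pulse metrics split the
   recording at pulse onsets (the last window runs to the end): waves per
   ROI, the trapezoidal area under the mean trace normalized to pulse 1,
   and the response latency (first 10%-crossing after onset) mean ± SD.

## The synthetic colony generator

Real microscopy recordings cannot ship with a package, so every stage is
validated against a generator that emulates the statistical structure of
protonemal calcium recordings with full ground truth.

**Geometry.** Filaments radiate from a common center as wiggling polylines
partitioned into cells (default length 80 ± 12 µm, truncated at 40 µm).
Each filament is caulonemal (width 14 µm) or chloronemal (19 µm) with equal
probability; the outermost cell is the tip (CA/CH), interior cells are
subapical (CAs/CHs), and cells that spawn side branches are typed B. Every
CA tip cell carries a 25 µm apical CA* sub-region. Cells are divided
lengthwise into regions of ~65 µm — the ground-truth ROIs, matching the
1–3 ROIs per cell that automatic segmentation recovers on real colonies and
a mean region area near the 150 px² segmentation prior.

**Wave program.** Each region draws a baseline F0 (300 ± 60 counts) and a
characteristic oscillation interval from a lognormal with mean 159.7 s and
across-ROI CV 45.4%; within a region, successive intervals jitter with CV
19.2%. These are the reported statistics of chitin-driven oscillations.
During a stimulus pulse the region fires first at onset plus a latency
drawn from a normal with SD 24 s whose mean drifts linearly across pulses
from 25 s (first) to 64 s (last) — the reported three-fold latency increase
over repeated stimulation — and then continues at its characteristic
interval while the stimulus stays on. Evoked amplitudes are 2.7 ± 0.6
ΔF/F0 and spontaneous ones 0.7 ± 0.2. CA* regions additionally oscillate
spontaneously before the first stimulus with median interval 85.5 s.
Other regions fire spontaneously at a low configurable rate (0.2 per
30 min, the long-adapted daytime figure). All waves respect a 30 s
refractory period; the shortest reported intervals (~59–63 s) imply
initiation suppression but no exact figure, so 30 s is a deliberately
conservative choice. Waves are Gaussian in time — the reported shapes are
bell-curved and symmetric — parameterized by FW10 (77 ± 15 s, truncated to
the reported 30–120 s range) via σ = FW10/(2√(2 ln 10)), which makes every
shape metric analytically checkable. Baselines rise by 25% at the first
stimulus onset and decay with τ = 600 s, mimicking the elevated post-onset
baseline.

**Rendering.** Pixel intensity is `background + Σ regions w · F0 · (1 +
baseline elevation + Σ waves A·exp(−(t−t_p)²/2σ²))`, where the membership
weight w is 1 in the filament core and falls as a cosine over the outer
2 px to a floor of 0.15 at the cell border (fluorescence is dimmest at
borders; the floor keeps every footprint pixel detectable, giving a hard
footprint edge with a graded interior). The frame is convolved with the
Gaussian PSF, then Poisson shot noise (gain 3 counts/photon) and Gaussian
read noise (SD 5) are applied — chosen for a per-pixel SNR of ~10 at
baseline, as the source protocol reports no camera statistics — and values
are rounded to 16-bit counts. With noise disabled the continuous
intensities are returned so closed-form checks are exact. Rendering and
deconvolution process frames in fixed-size chunks so peak memory stays
bounded regardless of recording length. Frames are sized to the colony
with a margin by default; a fixed frame size errors if the colony exceeds
it, naming the offending filament. No photobleaching, focus drift, stage
movement or multi-channel rendering is simulated.

**What passing tests do and do not show.** The generator reproduces the
*statistics* of real recordings (interval structure, latency drift, wave
shape, noise level) but not their artifacts: real colonies move slightly,
bleach, overlap at branch crossings, and have out-of-focus structure that
no 2D forward model captures. Recovery results (segmentation IoU, detector
recall) therefore demonstrate the algorithms' correctness under the stated
model, not their performance ceiling on arbitrary real data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col) = (y, x)`; time is frame index ×
  frame interval. CSV floats carry 6 significant digits, whole numbers are
  written as integers, and all writers have a fixed field order, so equal
  results are byte-identical on disk.
* The triangle threshold uses 256 bins over the data range; peak ties break
  toward the lower bin, distance ties toward the bin nearer the peak-side
  start of the scan. Constant images are a degenerate-input error.
* Cosine distance is undefined for zero-norm rows; flat pixels are held out
  of clustering and attached afterwards to the nearest centroid mean in the
  Euclidean sense.
* k-means ties (equal similarity to two centroids) resolve to the
  lowest-index centroid; with random initialization the event has measure
  zero and the fixed rule only serves determinism.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state, so a fixed seed is bit-reproducible regardless of
  session state.
* Stacks are written as 16-bit multi-page TIFF; float data (Z-scores) are
  affinely rescaled to [0, 1] for 32-bit storage with the offset/scale in a
  JSON sidecar, undone on read.

## Problem sizes

The test suite and the acceptance script validate on colonies of 14 regions
(unit tests, 600 s recordings), ~38 regions (segmentation robustness and
IoU, 1200 s), and 54–68 regions (entrainment, ten 60 s pulses every 240 s
over 2640 s, five seeds) — sizes chosen so the full suite exercises every
stage, including three full clustering passes and multi-seed entrainment
recovery, on a single CPU in well under half an hour.

## Known limitations

* The cluster count heuristic assumes ROIs near 150 px²; colonies imaged at
  very different magnifications need `mean_roi_area_px2` rescaled.
* Segmentation requires dynamics to differ between regions during the
  recording; constitutively bright or silent cells cluster arbitrarily and
  are only caught by the non-responsive exclusion rule.
* Wave-propagation velocity and direction are not estimated, and no
  hypothesis testing is included — standard statistics tooling applies
  directly to the wave tables the pipeline writes.
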