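---
title: "Quantifying nucleolar fluorescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar fluorescence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoquant)
```

## The problem

Nucleoli concentrate or exclude many nuclear molecules, and their
composition shifts with stress, drug treatment and transcriptional
activity. Measuring a probe's nucleolar concentration from fluorescence
micrographs requires (1) demarcating nucleoli without relying on any
single nucleolar "marker" protein - the classic markers themselves
relocate under stress - (2) suppressing noise and false positives, and
(3) measuring probe intensities inside the accepted segments after
background correction. `nucleoquant` implements this three-step workflow
with five interchangeable demarcation strategies, per-object statistics,
and a fully automated plate-scoring mode, plus a seeded synthetic-image
generator that provides ground truth for every claim the test suite
makes.

## Demarcation model

Nucleoli appear as *dark holes* in channels that stain the nucleoplasm
(DNA dyes such as DAPI; Pol II immunostains) and as dark *or* bright
regions in the probe channel. Demarcation converts those blobs into a
bright response image:

* **Dark holes** (methods 1-4): morphological bottom-hat, the grayscale
  closing with a disk minus the image. A hole of depth $d$ narrower than
  the disk produces a response plateau of height $d$; locally flat
  regions give 0.
* **Light holes** (method 5): the dual top-hat, image minus opening.
* **Method 3** first sums the two marker channels pixel-wise into a
  16-bit container (saturating at 65535, never rescaling, so hole
  contrast adds rather than distorts) and applies the bottom-hat to the
  sum. Adding markers raises hole contrast relative to a fixed noise
  floor, which is what makes the combination useful exactly when either
  single channel is marginal.

The disk diameter must exceed the largest expected hole so the closing
can roof over it; the default is 21 px, about 4.2 um at the default
0.2 um/px calibration, comfortably above a 5 um^2 nucleolus
(diameter ~2.5 um).

The commercial software this workflow models documents its erode filter
only as acting "depending on the number of black pixels in the
neighborhood", i.e. a rank filter with an unstated rank. We fix the rank
at its strictest value - any black neighbour blackens the pixel, which
is classical binary erosion - because classical morphology is exactly
reproducible; the erode-then-dilate pair with a diameter-6 disk is the
documented optimum and is the default for the binary noise-reduction
route.

## Noise reduction and segmentation

Two alternative noise filters precede segmentation, matching the two
protocols whose agreement the test suite verifies:

* **median**: the grayscale hole response is smoothed with a
  `width x height` median window (default 7x7, sub-sample ratio 1).
  With sub-sample ratio $s > 1$ the median is evaluated on an
  $s$-strided grid and the remaining pixels copy their nearest
  evaluated pixel - a speed/fidelity trade-off; the default $s = 1$
  path is exact.
* **erode/dilate**: the response is thresholded first, then the binary
  candidate mask is opened with the diameter-6 disk. Erosion removes
  speckle (at the cost of occasionally discarding small dim nucleoli);
  dilation restores the surviving regions to the extent of the actual
  nucleolus.

Candidate pixels must exceed the *local background* of the response by a
user-set intensity gate. The locality is per nucleus: the median
response inside the parent nucleus, recomputed once with first-pass
candidate pixels excluded so bright nucleoli do not inflate their own
background. In the probe-only HTS mode there is no nucleus mask and the
global median response serves as background. Accepted segments are
8-connected components inside nuclei whose area lies in the configured
window; labels are ordered deterministically top-to-bottom then
left-to-right by centroid, so reruns are bit-identical.

Nuclei themselves come from the nuclear-marker channel: 5x5 median
smoothing, a global Otsu threshold, hole-filling (so dark nucleoli
belong to their nucleus), 8-connected labeling, and a minimum-area
filter (default 40 um^2). Border-touching nuclei are kept for cell
counting but flagged. Nucleoli attach to the nucleus containing their
centroid; orphans are dropped and counted.

## Measurement

Only one operation ever touches the intensities that are measured:
*statistical correction*, which subtracts the mean of a cell-free region
(or, in HTS mode, the global mean of a cell-free background image) and
clamps at zero. All demarcation filters operate on separate response
images. Per nucleolus we report area (um^2 = pixel count x
pixel size^2), integrated intensity and mean intensity per um^2; per
nucleus, the filled-mask area and integrated intensity, the sums over
member nucleoli, the per-nucleus mean (summed intensity / summed area)
and the nucleolar/nuclear ratio.

Design choices that were genuinely open:

* The nucleolar/nuclear ratio uses *integrated* intensities (signals
  integrated over the entire nucleolus and nucleus); a per-area variant
  is available via `per_area = TRUE`.
* Mean intensities are normalized per um^2 rather than per pixel, so
  results are calibration-independent.
* Group comparisons default to the pooled-variance two-tailed Student's
  t-test, with Welch as a flag; more than two groups use one-way ANOVA.
  Degenerate all-equal groups return statistic 0 and p = 1 rather than
  erroring mid-batch.
* Nuclei with no detected nucleoli are excluded from per-nucleus
  analyses (they contribute no data point, but remain in the cell
  count).
* Histogram bins are shared across conditions by construction and are
  right-open except the last, which is closed so the maximum value is
  counted.

## HTS scoring and assay quality

Plate mode is fully non-interactive: light-hole detection on the
background-corrected probe, no nucleus-mask restriction, segments gated
to 2-5 um^2 and the intensity threshold, cells counted from the DAPI
channel. Sites within a well are pooled before well statistics. The
headline simple statistic is the percentage of nucleoli below 4 um^2,
which rises when drugs shrink nucleoli. Treatments normalize to their
mapped vehicle (water or DMSO) and are tested against it; the
replication unit defaults to whole experiments, with wells as an option,
because the choice is ambiguous in practice and both are defensible.

Assay quality is the screening-window statistic
$Z = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ with sample standard
deviations; $Z \ge 0.5$ is excellent, $0 < Z < 0.5$ moderate,
$Z \le 0$ unsuitable. Z is invariant under a common shift and positive
rescaling, which the suite checks, and simulated control wells converge
to the closed form as replicates grow.

## The synthetic-data generator

The generator is first-class, tested code - every validation claim in
the package is made against its ground truth. It renders:

* non-overlapping elliptical nuclei (semi-axes 5.5-7 um by default,
  HeLa-like) at a uniform marker level;
* 2-3 disk-shaped nucleoli per nucleus with areas uniform on 2-5 um^2
  (the screening window), rendered as *multiplicative* holes - marker
  level x (1 - hole depth), default depth 0.5 - so marker and probe
  contrasts scale together;
* a probe channel that is either enriched (nucleolar level =
  enrichment x nucleoplasmic level, default 2x) or depleted
  ((1 - depth) x), scaled further by a treatment effect multiplier and
  a per-nucleolus jitter factor N(1, 10%) that models real
  within-nucleus variability;
* background offset (default 2000), optional linear gradient, and
  seeded Gaussian noise with sigma = 2% of the dynamic range. Dynamic
  range here means the nuclear-marker level - the brightest rendered
  structure - not the 16-bit container maximum, so the noise floor is
  proportionate to the signal actually present.

Ground truth (masks and a per-nucleolus table of parent, centre, area
and noise-free probe level) is emitted before noise is added. Identical
parameters give bit-identical fields; the generator saves and restores
the caller's RNG state.

What the generator does *not* emulate - and hence what passing tests do
not show about real data: optical point-spread blur, nucleolar
substructure and fragmentation textures, chromatin texture inside
nuclei, spatially varying illumination beyond a linear gradient, and
cell-cycle morphology. Results on synthetic fields bound algorithmic
correctness, not biological image difficulty.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-based `(row, col)`; areas are only ever
  reported in um^2.
* Median windows truncate at the raster border; erosion treats
  out-of-bounds as white and dilation as black, so borders behave
  neutrally and a constant image is a fixed point of every filter.
* Background subtraction clamps at 0 (intensities are physical counts);
  corrected images may hold fractional values and integer-valued rasters
  are enforced only at TIFF write time.
* Object labeling is 8-connected everywhere (small blob-like objects;
  avoids splitting diagonal necks); label sets are always contiguous
  `1..K`.
* Parent assignment ties (centroid pixel on a boundary) resolve to the
  nucleus label at the rounded centroid; nucleoli outside every nucleus
  are dropped and counted, never silently lost.
* Blank images segment to empty masks, empty segmentations measure to
  empty tables, and empty area lists make `fraction_small()` return
  `NA` with a warning - none of these abort a batch.
* A calibration note on gates: segment boundaries are quantized to
  pixels, so a measured area can differ from the underlying object's
  by up to roughly a 1-pixel ring (10-20% for 2-5 um^2 objects at
  0.2 um/px). Area windows therefore act on *measured* areas; objects
  generated exactly at a window edge can legitimately fall on either
  side of the gate. Validation fixtures that assert complete recovery
  keep their truth areas clear of the configured gates for this reason.

## Default parameter calibration

Segmentation defaults (intensity gate 4000 on 16-bit responses, area
window 1-8 um^2 for interactive use, 2-5 um^2 in HTS mode, disk
diameter 21 px, median 7x7) were chosen once for the default generator
conditions - marker level 20000, hole depth 0.5, noise sigma 400 - in
the same way a microscopist tunes the software's thresholds on
representative images before a run: the gate sits well above the
smoothed noise floor and below the expected response depth
(depth x marker level = 10000). For the low-contrast marker-comparison
study (hole depth 0.25) the gate drops to 2000 by the same rule. These
are method tunables, expected to be re-calibrated per assay; the
generator's own parameters are study conditions and are never adjusted
to fit an expected outcome.

Problem sizes used by the validation suite - one 768 px reference field
(20 nuclei, ~50 nucleoli), ten low-contrast fields for the
marker-ordering study, 500 truth nucleoli for the area-distribution
check, 30 objects per condition for effect recovery, and 10^4 simulated
wells for Z-factor convergence - were chosen so each estimate's sampling
error is comfortably below the property being asserted.

## Worked example

```{r example, eval = FALSE}
field <- generate_field(synth_params())
res <- run_method(field$channels, segmentation_params(method_id = 1),
                  correction = list(roi = c(0, 0, 30, 30)))
head(res$nucleoli)

ev <- evaluate_detection(res$segmentation$nucleolus_mask,
                         field$truth$nucleolus_mask)
c(recall = ev$recall, precision = ev$precision)
```

## Known limitations

* 2-D single-plane images only; no z-stacks, time series or proprietary
  microscope formats (multi-channel input is per-wavelength TIFFs plus a
  role manifest).
* Nucleus segmentation is a reconstruction (Otsu + hole filling); very
  low-contrast or touching nuclei are not split by watershed or any
  learned model.
* No flat-field correction, deconvolution or rolling-ball background;
  the statistical correction removes a spatially constant background
  only, so strong uncorrected gradients bias intensities.
* The nucleolar substructure (FC/DFC/GC) is out of scope, as is
  cytoplasmic quantification beyond the nucleolar/nuclear ratio.
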