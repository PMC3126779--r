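# nucleoquant

Computer-based quantification of fluorescence in **nucleoli** — the
membrane-less nuclear compartments of ribosome biogenesis that appear as
dark holes in DAPI-stained nuclei and as dark or bright regions in a probe
channel. The package is for microscopists and screeners who need to
measure how much of a probed molecule (an immunostained protein, a GFP
fusion, or EU-labeled nascent RNA) sits in nucleoli, per nucleolus, per
nucleus, per condition, and at plate scale — without depending on any
single nucleolar marker protein, since the classic markers themselves
relocate under stress.

## What it computes

Quantification is a three-step workflow:

1. **Detection and demarcation.** Five interchangeable strategies turn
   nucleoli into bright response blobs:
   - methods 1–4: morphological *bottom-hat* (grayscale closing with a
     disk, minus the image) on the DAPI channel, a second nucleoplasmic
     marker (e.g. Pol II), the saturating 16-bit *sum* of both markers, or
     the probe itself;
   - method 5: the dual *top-hat* on the probe, for probes concentrated in
     nucleoli.
2. **Noise reduction.** Either a rectangular median filter on the
   grayscale response, or threshold-then-open (binary erode/dilate with a
   diameter-6 disk).
3. **Segmentation and measurement.** 8-connected components above a
   per-nucleus local-background intensity gate, filtered to an area window
   in µm², attached to the nucleus containing their centroid, and measured
   on the *statistically corrected* probe (mean of a cell-free region or
   background image subtracted, clamped at 0 — the only operation that
   ever touches measured intensities).

Per nucleolus: area (µm²), integrated and mean intensity (per µm²). Per
nucleus: nucleolar sums, per-nucleus mean, and the nucleolar/nuclear
ratio of integrated intensities. Per condition: normalized means (control
= 1) with Student's *t* / one-way ANOVA, shared-bin histograms, and the
within-nucleus variability percentage. For high-throughput screening:
probe-only scoring of light holes in the 2–5 µm² window, nucleoli/cell,
the percentage of nucleoli below 4 µm², per-treatment normalization to
water/DMSO vehicles, and the assay-quality Z-factor

> Z = 1 − 3(σ₊ + σ₋) / |μ₊ − μ₋|,  Z ≥ 0.5 ⇒ excellent.

A seeded synthetic-field generator (elliptical nuclei, disk nucleoli as
multiplicative dark holes, enriched/depleted probe, background + Gaussian
noise) provides ground-truth masks for every validation claim.

## Worked example

```r
library(nucleoquant)

field <- generate_field(synth_params())          # 20 nuclei, ~50 nucleoli
res <- run_method(field$channels, segmentation_params(method_id = 1),
                  correction = list(roi = c(0, 0, 30, 30)))
head(res$nucleoli[, 1:5])
#>   nucleolus_id nucleus_id area_um2 integrated_intensity mean_intensity
#> 1            1         16     2.96              1379103         465913
#> 2            2         16     2.04              1320508         647308
#> 3            3         17     3.56              1770001         497191
#> 4            4         17     4.00              1999170         499793
#> 5            5          9     1.88              1032206         549046
#> 6            6         16     2.16              1135097         525508
```

Each row is one accepted nucleolus: its parent nucleus, area in µm², the
summed corrected-probe intensity inside it, and that sum per µm². Checked
against the generator's truth masks:

```r
ev <- evaluate_detection(res$segmentation$nucleolus_mask,
                         field$truth$nucleolus_mask)
c(recall = ev$recall, precision = ev$precision)
#>    recall precision
#>         1         1

within_nucleus_variability(res$nucleoli)
#>   condition n_nuclei stdev_pct
#> 1       all       20  10.17548
```

All 50 generated nucleoli are recovered with no false positives, and the
measured within-nucleus variability (10.2%) recovers the generator's 10%
jitter. Assay quality for a screen:

```r
z_factor(c(95, 100, 105), c(15, 20, 25))
#> Z-factor: 0.625 (excellent)
#>   positive controls: mean 100, sd 5
#>   negative controls: mean 20, sd 5
```

A thin command-line front end wraps the same functions for batch use:

```sh
Rscript inst/cli/nucleoquant.R synth     --config synth.yaml --out fields/
Rscript inst/cli/nucleoquant.R quantify  --config run.yaml   --out results/
Rscript inst/cli/nucleoquant.R hts-score --layout plate.yaml \
        --images imgdir/ --background bg.tif --out plate_results/
Rscript inst/cli/nucleoquant.R compare   --control DMSO --by nucleolus \
        results/*.csv
```

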