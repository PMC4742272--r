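# chromoscore

Morphometric analysis of cardiomyocyte nuclear chromatin in transmission
electron micrographs, for pathologists and cardiology researchers studying
severe dilated cardiomyopathy (DCM). In endomyocardial biopsies, the state
of the electron-dense chromatin rim lining the inner nuclear envelope
(perinuclear condensed chromatin) stratifies prognosis: nuclei with a
*discontinuous* rim (Group A) mark patients at very high 12-month risk of
ventricular-assist-device implantation or cardiac death, while patients
with *continuous* rims (Group N) are further stratified by two
morphometric scores. chromoscore implements this two-step procedure as a
tested R library plus a command-line interface.

## The method

All images are 8-bit grayscale (digital numbers, DN 0–255), brightness-
calibrated so the sarcomeric Z-disk — an internal reference — lands at a
target mean of DN 159 (window 154–164) via a gain-only map. Then:

**Step 1 — continuity.** The perinuclear rim is the largest 8-connected
component of `DN >= 145` in the nucleus ROI after a 1-px morphological
closing. A nucleus is *continuous* iff hole-filling the rim encloses an
interior of at least 500 px; otherwise it is Group A (high-risk).

**Step 2 — chromatin scores** (continuous nuclei only), with condensed
chromatin defined as the top grayscale quartile `DN >= 192`:

    Nuc-CS = 100 * |condensed ∩ (interior \ nucleolus)| / |interior \ nucleolus|   (%)
    Per-CS = |condensed ∩ rim| / inner nuclear perimeter                           (px)

Low values of either score mark the Group N patients at elevated risk. The
package also measures percent interstitial fibrosis from Masson-trichrome
RGB scans (HSV blue-band detection), provides the cohort statistics layer
(t / Mann-Whitney tests, 2×2 outcome tables with chi-square and Fisher,
ROC/AUC with DeLong intervals, interobserver ICC(2,1)), and ships a seeded
synthetic generator of EM-like nuclei, cohorts and trichrome slides with
analytic ground truth.

## Worked example

```r
library(chromoscore)

## a synthetic, pre-calibrated nucleus with exact ground truth
gen <- generate_nucleus(nucleus_spec(seed = 5))
seg <- segment_nucleus(gen$image, gen$truth$roi)
seg
#> <nucleus_segmentation (unnamed): continuous (N), ring 1588 px, interior 11304 px,
#>  nucleolus 716 px, inner perimeter 378.2 px>

cfg <- threshold_config()
compute_nuc_cs(gen$image, seg, cfg)   # 3.54  (% nucleoplasm condensed; truth 3.54)
compute_per_cs(gen$image, seg, cfg)   # 4.20  (px effective rim thickness; truth 4.13)

## outcome statistics from a 2x2 table of 12-month events by group
tbl <- rbind(A = c(11, 0), N = c(7, 45))
res <- event_rate_test(tbl)
res$rates_rounded                     # 100 13   (% events per group)
res$p                                 # 5.2e-08  (Fisher, two-sided)
```

The segmentation line says the rim was isolated (1588 px), it encloses a
nucleoplasm (continuous → Group N), and the nucleolus (716 px) was found
and excluded; the scores then land within rasterization error of the
generator's analytic expectations. The 2×2 table reproduces the 100% vs
13% event rates, different at p < 0.01.

The CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/chromoscore.R", package = "chromoscore"))')
Rscript $CLI simulate nucleus --seed 5 --out sim
Rscript $CLI segment --image sim/nucleus.png --roi sim/roi.png --out-prefix seg
Rscript $CLI score   --image sim/nucleus.png --roi sim/roi.png --out scores.csv
```

Subcommands: `calibrate`, `segment`, `score`, `fibrosis`, `cohort`,
`simulate`, `run` (batch processing with per-item fault isolation and a
reproducibility manifest).

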