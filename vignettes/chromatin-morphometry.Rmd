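---
title: "Nuclear chromatin morphometry: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear chromatin morphometry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscore)
```

## The measurement problem

In severe dilated cardiomyopathy, the ultrastructure of cardiomyocyte
nuclear chromatin — visible in transmission electron micrographs of
endomyocardial biopsies — carries prognostic information. Two phenotypes are
distinguished. In one, the electron-dense chromatin rim lining the inner
nuclear envelope (perinuclear condensed chromatin) is *discontinuous*, with
signal defects along the nuclear border and aggregated nucleoplasmic
particles (Group A). In the other the rim is *continuous* and the nucleus
can be cleanly delineated (Group N). For continuous nuclei, two morphometric
scores summarize the chromatin state:

* **Nuc-CS** (nucleoplasmic chromatin score, %) — the fraction of the
  nucleoplasm, excluding the nucleolus, occupied by condensed chromatin:
  $$\mathrm{NucCS} = 100 \cdot
    \frac{|\{\text{condensed}\} \cap (\text{interior} \setminus \text{nucleolus})|}
         {|\text{interior} \setminus \text{nucleolus}|}$$
* **Per-CS** (perinuclear chromatin score, px) — the condensed area of the
  rim per unit inner nuclear perimeter, an effective rim thickness:
  $$\mathrm{PerCS} =
    \frac{|\{\text{condensed}\} \cap \text{rim}|}{\text{inner perimeter}}$$

chromoscore implements the full chain — grayscale calibration, rim
extraction, continuity classification, score computation, percent-fibrosis
measurement from trichrome scans, and the cohort statistics — plus a
synthetic generator that makes every stage testable without real
micrographs.

## Intensity scale and thresholds

Micrographs are 8-bit grayscale. The imaging convention the method was
defined on counts 256 grayscale values starting at 1; the package stores
digital numbers (DN) 0–255 and converts every published threshold by
subtracting 1, applying it inclusively as `DN >= t`:

| parameter | default | meaning |
|---|---|---|
| `t_peri` | 145 | perinuclear condensed chromatin band (published 146–256) |
| `t_cond` | 192 | condensed chromatin, top quartile (published 193–256; DN ≥ 192 spans exactly 64 of 256 values) |
| `zdisk_lo`, `zdisk_hi` | 154, 164 | acceptance window for the calibrated Z-disk mean (published 155–165) |
| `zdisk_target` | 159 | calibration target (window midpoint) |

Whether the original software's scale ran 0–255 or 1–256 is not documented
anywhere we could find; the subtract-one convention is a deliberate,
documented choice that preserves the top-quartile semantics, and every
threshold is overridable through `threshold_config()`.

## Z-disk calibration

Absolute brightness varies between micrographs, so chromatin DN are only
meaningful relative to an internal reference: the sarcomeric Z-disk.
`calibrate_to_zdisk()` applies a gain-only map
`out = clamp(round(g * DN))` with `g = zdisk_target / mean(ROI)`. A
multiplicative (ratio) map was chosen over a full affine map because the
chromatin signal is treated as a value *relative to* the Z-disk, and a
gain-only map preserves DN 0 = no signal. The map is monotone, idempotent
to ±1 DN (rounding), and fails loudly when the recalculated ROI mean cannot
reach the acceptance window (saturated images). Clipping more than 1% of
pixels at DN 255 triggers a warning but not an error.

## Continuity as topology

The original description of the discontinuous phenotype is operational:
such nuclei "cannot be clipped out" of the image. That is exactly failure of
topological enclosure, so the package defines continuity without any gap-arc
measurement:

1. threshold at `t_peri` inside the nucleus ROI,
2. morphological closing with radius `closing_radius` (default 1 px,
   absorbing hairline staining cracks),
3. keep the largest 8-connected component (the rim),
4. the nucleus is continuous iff hole-filling that component yields an
   enclosed interior whose largest component has at least
   `min_interior_area` pixels (default 500 px, tuned to 10,000×
   magnification; it rejects speck enclosures).

Foreground components use 8-connectivity and background (hole) detection
4-connectivity — the standard complementary pair that avoids topological
paradoxes. The hole-filling rule is provably equivalent to "flood fill of
the background from the image border never reaches an interior pixel", and
the test suite checks the two formulations against each other.

The nucleolus — equally electron-dense — is detected inside the interior as
the largest condensed component covering at least `nucleolus_min_frac`
(default 5%) of the interior; scattered chromatin specks never qualify. The
original workflow does not state whether nucleolus exclusion was manual or
automatic, so an externally supplied mask always overrides detection.

## Numerical choices

**Inner perimeter.** The interior boundary is traced at the 0.5 iso-level
between inside and outside pixel centers (marching squares, via
`contourLines`). The raw midpoint polygon systematically overestimates
smooth boundaries by ~5–8% (staircase bias), so the closed vertex chain is
smoothed by two circular moving-average passes (window 3) before summing
segment lengths. This leaves straight and 45° stretches unchanged, brings a
digital disk of radius 100 px within 0.5% of $2\pi r$ and a 50-px square
within 2% of $4s$, and still returns a small positive length for a single
pixel. The pass count is an argument of `contour_perimeter()`.

**Two thresholds, one rim.** Per-CS needs "condensed area of the
perinuclear chromatin", but the rim is isolated at `t_peri` while
"condensed" is defined at `t_cond`. The package restricts the condensed
count to the rim mask (`DN >= t_cond` within the component found at
`t_peri`), which is the only reading that reconciles the two bands.

**Patient aggregation.** The per-patient score is the arithmetic mean over
that patient's continuous nuclei; the within-patient variability report
carries the median and 10th/25th/75th/90th percentiles (the box-plot
summary). Mixed continuity verdicts within a patient are resolved by
majority vote and flagged, since observed specimens are phenotype-pure.

**Two-step stratification.** Group A is high-risk unconditionally. Group N
patients are flagged elevated-risk when *either* patient-level score falls
at or below its cutoff (OR rule — each score is treated as independently
discriminative, and low values are the risk direction). No cutoffs ship as
defaults: the observed score ranges are not validated decision thresholds,
so with `NULL` cutoffs the function is report-only.

## Cohort statistics

* `compare_continuous()` — pooled-variance t-test or Mann-Whitney U. The U
  test enumerates the full permutation distribution (on midranks, so ties
  are exact) whenever `choose(n1+n2, n1) <= 2e5`, and otherwise uses the
  tie-corrected normal approximation.
* `event_rate_test()` — 2×2 outcome tables; event percentages are rounded
  half-up to integers (table-presentation convention). Chi-square is
  computed without continuity correction; Fisher's exact test is the
  automatic choice when any expected count is below 5 (the typical case
  here, since the discontinuous group can have a zero cell).
* `roc_auc()` — the AUC is the all-pairs concordance (midrank identity,
  ties counted ½), with an explicit, never auto-flipped orientation; for
  both chromatin scores *low* values predict events. The 95% CI is
  DeLong's.
* `icc_agreement()` — ICC(2,1): two-way random effects, absolute agreement,
  single measures, the standard interobserver form, with the F-based
  McGraw–Wong interval. The CI method used in the original report is not
  identifiable from its asymmetric intervals; the F-based ANOVA interval is
  the defensible default.

## The synthetic generator

`generate_nucleus()` renders what the method needs and nothing more: a
dense rim (annulus, optionally with gap arcs — the discontinuous
phenotype), granular condensed particles in the nucleoplasm, a central
nucleolus, Z-disk reference stripes in the background margin, and optional
truncated Gaussian noise. Defaults: 160×160 px, inner radius 60 px, rim
thickness 4 px, rim DN 210, particle DN 230, nucleolus DN 220 (all above
`t_cond`), nucleoplasm DN 100, background DN 50, stripes at DN 159 so the
phantom ships pre-calibrated. With ~3 particles per 1,000 interior px and
rim thickness 2.3–6 px, the analytic scores fall in the 1–9% / 2.3–6.3 px
ranges reported for real Group N nuclei.

Ground truth is exact: masks are the noiseless geometry,
`expected_nuc_cs` uses the realized rasterized particle area, and
`expected_per_cs` is fully analytic, $t(1 + t/2r)$ — rasterization error is
deliberately left inside the recovery tolerance rather than absorbed into
the expectation. Two placement details matter: particles stay ≥ 6 px clear
of the rim so the ring-extraction closing can never weld them to it, and
the ground-truth ROI is an *annular* neighborhood of the nuclear envelope
(the way an annotator outlines a nuclear border), so the nucleolus — whose
area can exceed a thin rim's — never competes for the largest thresholded
component.

`generate_cohort()` mirrors the study design the method was developed on:
11 discontinuous-rim patients (all with 12-month events) and 52
continuous-rim patients of whom 7 have events, ~10 nuclei per patient
(Poisson, minimum 3). Generative score levels for Group N are drawn from an
event stratum (particle density 0.9–2.0 per 1,000 px, rim thickness
2.3–2.8 px) and a non-event stratum (2.6–6.5 and 3.4–6.0), echoing the
reported event/non-event score ranges; the default strata do not overlap,
so the score–event link is perfectly separated and the pipeline's Group N
ROC AUC is 1 by construction. Covariates (age, LVEF, LVEDD, BNP, fibrosis)
are drawn from group-specific distributions typical of a severe-DCM biopsy
cohort. `generate_trichrome()` builds a tissue disc with blue collagen
blobs grown to a target fraction and reports the exact realized fraction.

What the generator does **not** emulate: real EM texture (sarcomeres beyond
Z-disk stripes, mitochondria, staining gradients), irregular nuclear
outlines, partially fuzzy borders, or fibroblast/endothelial nuclei — the
visual cell-type verification step of the real workflow has no synthetic
counterpart. Passing the recovery suites therefore demonstrates that the
*measurement chain* is correct, not that the thresholds generalize to any
particular microscope or staining protocol.

## Problem sizes and verification scope

The test suite and the acceptance script verify, among others: score
recovery over 100 seeded noiseless nuclei (Nuc-CS within ±1 point, Per-CS
within ±0.2 px of the analytic expectations); continuity agreement with the
generator's gap flags over 200 nuclei noiseless and 200 at noise σ = 8 DN
(gap arcs ≥ 5°); the calibration contract over random Z-disk ROI means in
40–220 DN; oracle equivalence of the statistical kernels (AUC vs all-pairs
concordance, exact U vs full enumeration, Fisher vs hypergeometric
enumeration, duplicate-rater ICC = 1); and an end-to-end 63-patient
synthetic cohort classified 11/52 with AUC 1 under the separated
score–event link. These sizes were chosen to exercise each contract
meaningfully at interactive runtimes.

## Known limitations

* The Per-CS pixel unit is magnification-bound (10,000×); no
  cross-magnification normalization is attempted.
* One nucleus per ROI; multi-nucleus fields must be pre-split.
* No automatic nucleus detection, no cardiomyocyte-vs-fibroblast
  discrimination, no endocardium auto-detection on trichrome scans.
* The exact discontinuity detector and blue-detection rule of the original
  commercial software are unpublished; the topological and HSV-band
  definitions here are documented reinterpretations, with every parameter
  exposed in configuration.
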