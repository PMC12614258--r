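---
title: "Longitudinal grid-box quantification of choriocapillaris flow deficits: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal grid-box quantification of choriocapillaris flow deficits: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfdgrid)
```

## The problem

Choroidal hypertransmission defects (hyperTDs) — focal bright areas on en
face sub-RPE OCT slabs with a greatest linear dimension of at least
250 µm — mark attenuation or loss of the retinal pigment epithelium and
are an early harbinger of geographic atrophy in age-related macular
degeneration. A central question for trial design is whether loss of
choriocapillaris (CC) perfusion *precedes* hyperTD formation or follows
it. This package implements the measurement machinery needed to answer
that question longitudinally from swept-source OCT angiography: per-visit
CC flow-deficit (CCFD) quantification, registration of four annual visits
onto a common frame, a grid of 74 × 74-pixel boxes tracked across visits,
a 5-percentage-point minimal-detectable-change (MDC) rule for single
boxes, and nested mixed models for group-level contrasts.

Because the clinical scans behind the question are not public, the
package ships a synthetic scan generator with known ground truth for
every stage; all validation is against that truth.

## Pipeline

Each visit provides four en face rasters (CC flow, CC structure, sub-RPE
structure, retinal vasculature; default 500 × 500 px at 12 µm/px from a
6-mm scan with 500 A-scans) plus manual masks: an exclusion mask for
hypotransmission defects (hypoTD; calcified drusen and hyperreflective
foci shadow the CC and make it unquantifiable) and a hyperTD annotation.

1. **Low-signal mask.** Background level is the median of the darkest 5%
   of CC-structure pixels; pixels below `10^(5/10)` × background (5 dB)
   are unavailable. The mask is computed on the *uncompensated*
   structure slab: signal quality is a property of the acquired signal,
   and compensation amplifies noise-floor regions toward tissue level
   without adding information. (On a raster with no true noise-floor
   population — e.g. a constant image — this estimator necessarily masks
   everything; the 5-dB rule presumes scans whose darkest pixels are
   genuinely background, which real exports and the generator both
   provide.)
2. **Compensation.** Drusen attenuate the CC signal. The sub-RPE
   structure slab, smoothed with a truncated 13 × 13 Gaussian (σ = 15 px,
   reflective borders, ε-floored), is normalized by its 99th percentile
   into `N(x) ∈ [1e-3, 1]` and the CC slabs are multiplied by
   `N(x)^(-γ)`. The normalization percentile is estimated *outside* the
   hyperTD compensation mask: the ceiling must represent unattenuated
   normal tissue, and with a large lesion the bright hyperTD halo would
   otherwise capture it and mis-scale every normal pixel. γ is chosen
   per scan from a 0–5 grid (step 0.1, ties to the smaller γ) by
   minimizing the standard deviation of the compensated CC structure
   over eligible pixels — outside the hyperTD mask, the exclusion mask,
   and the low-signal mask. Two numerical choices matter here:
   the objective uses *unclipped* compensated values (clipping inside
   the objective lets large γ push every pixel to the ceiling and
   collapse the sd to zero, so the argmin saturates at the top of the
   grid), and noise-floor pixels are excluded from the objective
   (they respond to the factor without carrying signal and otherwise
   dominate it, dragging γ to zero). Compensated slabs exported to
   disk are clipped at the input slab's maximum to bound shadow
   amplification. HyperTD pixels are never compensated (factor 1):
   compensating a bright lesion inverts it into artifactual deficits.
3. **Binarization.** Two-cluster fuzzy C-means (fuzzifier m = 2) on a
   256-bin histogram of valid pixels, centers initialized at the
   25th/75th percentiles, converged at 1e-6 or 500 iterations; the
   threshold is the midpoint of the converged centers (the
   equal-membership point for m = 2). Pixels strictly below the
   threshold are deficits. The histogram formulation makes the
   threshold a deterministic functional of the intensity distribution.
   Deficit components (8-connected) with equivalent circular diameter
   `2·s·sqrt(area/π)` under 24 µm — the physiological intercapillary
   distance — are reassigned to flow. "Size" is not otherwise defined
   for this filter; equivalent diameter gives crisp, testable
   boundaries (a 3-px component at 12 µm/px is 23.4 µm and is removed;
   4 px is 27.1 µm and kept).
4. **Registration.** Each visit's vasculature image is aligned to the
   *final* visit by integer translation, scored by exact zero-normalized
   cross-correlation between the reference's central template and every
   candidate window (|dy|, |dx| ≤ 32 px), computed for all shifts at
   once via FFT cross-correlation plus integral-image window statistics.
   Ties break toward the smaller |dy|+|dx|; a peak below 0.2 marks the
   case unregisterable (excluded, with the reason recorded). Transforms
   propagate to CCFD maps (border fill: invalid) and masks (exclusion
   masks fill TRUE, annotations FALSE). Per-visit registered exclusion
   masks are unioned into one *integrated* mask applied to every visit,
   so the same regions are excluded throughout the study. Rotation and
   scaling are out of scope: fovea-centered follow-up scans are
   nominally aligned and the residual is a translation.
5. **Grid.** A 74 × 74-px target box (~0.9 × 0.9 mm, 0.81 mm²) is
   centered on the rounded centroid of the target-hyperTD annotation
   (clamped inside the raster), and a lattice of complete boxes anchored
   at the target extends across the image. The target box is `target`;
   any other box overlapping any hyperTD pixel at any visit (including
   target-lesion spillover) is `nontarget_hypertd`; remaining boxes are
   `adjacent_background` when they share an edge or corner on the box
   lattice with a hyperTD box, else `nonadjacent_background`.
   Categories are frozen across visits. A box with more than 25% of its
   area unavailable (invalid ∪ low-signal; the union, since either
   condition alone invalidates a pixel) at *any* visit is excluded at
   all visits — the study-wide analogue of the integrated mask. Box
   CCFD% is `100 × deficit / (deficit + flow)` over available pixels.
6. **MDC tracking.** Per box, change versus the pre-onset visit is
   flagged when |Δ| strictly exceeds 5 points, a round bound over the
   published 4.67% single-box MDC.
7. **Group inference.** CCFD% ~ visit (categorical) with nested random
   intercepts for patient, eye within patient, and box within eye, fit
   by REML (`lmerTest`). Intercepts whose grouping factor is
   unidentifiable (single level, or confounded with the level above)
   are dropped up front; an intercept estimated at zero variance
   (singular fit) is removed and the model refit. Contrasts of each
   visit against onset use Satterthwaite degrees of freedom and Tukey
   adjustment over the full family of six pairwise visit comparisons
   (standard Tukey semantics, even though only three contrasts are
   reported). Reported intervals are unadjusted 95% CIs next to
   adjusted p-values, and are labelled as such.

## The synthetic generator

`generate_case()` renders anatomy once on a padded canvas and crops each
visit at a known integer translation, so registered visits are
pixel-identical in their interiors:

- **Deficits** are a hard-core disc process: discs of radius 2 px
  (48-µm diameter, safely above the 24-µm filter) on a jittered 6-px
  lattice, kept with the probability that yields the target deficit
  fraction (default 10%). Discs stay clear of every visit's crop window
  so no true component is clipped below the filter scale. A `speckle`
  option plants single-pixel false deficits to exercise the filter.
  Deficit pixels keep a residual decorrelation floor
  (`deficit_contrast` = 0.4 × baseline): OCTA deficits are not true
  zeros, and this is what gives the binarization step a realistic
  margin rather than an infinite one.
- **Drusen attenuation** is a product of Gaussian bumps (default 15,
  σ = 300 µm, depth 0.55), placed non-overlapping (hard-core 2.2σ):
  stacked bumps would produce attenuation deeper than discrete drusen
  warrant. Flow and structure slabs share the field; the hyperTD
  region is never attenuated (RPE loss increases transmission).
- **The hyperTD** appears at visit 1 with GLD ≥ 250 µm (default radii
  0/150/220/300 µm) as doubled sub-RPE brightness; **hypoTDs** are
  near-zero discs in all slabs, copied into the exclusion mask.
- **The vasculature** is a branching random tree, identical across
  visits up to the known translation (and unvignetted, as the retinal
  layers are better illuminated), which makes exact shift recovery a
  meaningful test.
- **Noise and variability.** Per-visit Gaussian noise is
  heteroscedastic — sd proportional to the clean signal plus a small
  dark floor, truncated at zero — as OCT speckle statistics are, and a
  smooth multiplicative illumination field (sd 5%, 25-px scale) varies
  between visits, emulating the scan-to-scan variability that drives
  CCFD% test-retest error. An instrument-frame vignette band (outer
  25 px at 5% signal) gives each scan a genuine noise floor, which the
  5-dB background rule requires. In the *null* scenario the deficit
  field is constant across visits and only noise and illumination
  change; in the *effect* scenario the deficit fraction inside a
  1300-µm lesion neighborhood rises (default to 25%) at the two
  post-onset visits.

What the generator does **not** emulate: physical OCT speckle
correlations, B-scan acquisition artifacts (motion stripes,
defocus), segmentation error in the slabs, eye-specific axial-length
scaling, and drusen that grow or regress between visits. Passing the
validation suite therefore shows the *algorithmic* chain is correct and
calibrated under controlled conditions — not that the clinical
performance on real scans is reproduced.

## Validation design and problem sizes

The test and acceptance suites validate each stage against independent
oracles: a dense-loop convolution for the smoothing kernel; exhaustive
FCM-objective minimization over all candidate center pairs for the
threshold; a 10×-finer brute-force grid for γ; known translations for
registration; counted truth masks for box CCFD%. Study-level checks use
sizes chosen to finish in minutes on one core while keeping Monte-Carlo
error well inside the asserted bands: 50 histograms for the FCM
agreement, 51 vasculature pairs for registration, 20 seeds × 2 scenarios
for parameter recovery, a 200-eye null cohort for the MDC rule, 100
replicates of the full 24-patient × 27-box design for effect recovery
and CI coverage, 300 null replicates of a 12 × 10 design for Tukey
calibration, and an 8-eye effect cohort for the qualitative
significance pattern. The Tukey null check asserts the *family-wise*
rejection rate of the six-contrast family (nominally 5%); a single
Tukey-adjusted contrast is necessarily more conservative (~1%) and is
checked only against the upper bound.

## Known limitations

- Integer-translation registration cannot express rotation, scaling, or
  subpixel shifts; residual misalignment in real data would appear as
  box-level noise that the synthetic arm does not contain.
- The compensation model is en face and multiplicative; depth-resolved
  attenuation (per-A-scan) correction is out of scope.
- Retinal-vessel projection artifacts are handled by exclusion (vessel
  mask pixels are invalid) rather than modelled removal.
- The darkest-5% background estimator assumes the scan has a real
  noise-floor population; on degenerate homogeneous rasters it masks
  the whole image by construction.
- With the generator's defaults the synthetic test-retest variability
  of a target box is smaller than published single-box repeatability,
  so the null MDC check exercises the 5% rule as an upper bound (the
  null flag rate it measures sits near zero) rather than reproducing
  clinical repeatability quantitatively.
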