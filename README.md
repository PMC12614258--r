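# ccfdgrid

Longitudinal grid-box quantification of choriocapillaris flow deficits
(CCFD) on en face swept-source OCT angiography.

## The problem

Large choroidal hypertransmission defects (hyperTDs) — focal bright
lesions with a greatest linear dimension ≥ 250 µm on en face sub-RPE
slabs — are an early harbinger of geographic atrophy in AMD. Whether
loss of choriocapillaris perfusion *precedes* hyperTD formation or
follows it matters for treatment timing, and answering it requires
measuring small longitudinal changes in CCFD% at exactly the same
retinal location across annual visits. This package implements that
measurement chain for researchers working with en face OCTA exports:

- **γ-optimized attenuation compensation.** The CC slabs are multiplied
  by `N(x)^(−γ)`, where `N` is the smoothed sub-RPE structure slab
  normalized by its 99th percentile; γ is selected per scan by
  minimizing the standard deviation of the compensated CC structure
  over eligible pixels. HyperTD regions are protected from
  compensation so bright lesions are not inverted into artifactual
  deficits.
- **Fuzzy C-means binarization.** A 2-cluster FCM (m = 2) on the
  intensity histogram sets a global threshold at the equal-membership
  point `(c_low + c_high)/2`; deficits smaller than the 24-µm
  intercapillary distance (equivalent diameter `2·s·sqrt(A/π)`) are
  removed.
- **Registration and grid tracking.** Visits register to the final
  visit by exact zero-normalized cross-correlation of the retinal
  vasculature (integer translation, search radius 32 px); exclusion
  masks merge into one integrated mask; a 74 × 74-px box grid
  (≈ 0.9 × 0.9 mm) anchored on the target lesion tracks CCFD% per box,
  with boxes > 25% unavailable at any visit excluded study-wide.
- **Change detection and inference.** Single-box changes are flagged
  against a 5% minimal detectable change; group contrasts come from
  `ccfd_pct ~ visit + (1|patient) + (1|eye) + (1|box)` (REML,
  Satterthwaite df, Tukey adjustment over all six visit pairs).
- **A synthetic scan generator** with known ground truth (drusen
  attenuation, lesion onset and growth, hypoTD shadows, known
  inter-visit shifts, known per-box deficit fractions) stands in for
  clinical scans and backs the entire validation suite.

## Worked example

```r
library(ccfdgrid)

cfg  <- ccfd_config()                       # 74-px boxes, 12 µm/px, γ ∈ [0,5] ...
case <- generate_case(scenario_params(deficit_fraction_post = 0.25,
                                      rng_seed = 42))
res  <- run_case(case$visits, cfg)

sapply(res$meta, `[[`, "gamma_star")        # per-visit optimal γ
res$target_mdc                              # target-box change vs baseline
```

Output from this run:

```
> sapply(res$meta, `[[`, "gamma_star")
[1] 0.6 0.5 0.5 0.6
> res$target_mdc
  visit_index       delta marked_change
1           0  0.00000000            NA
2           1  0.03652301         FALSE
3           2 14.66398831          TRUE
4           3 14.88312637          TRUE
```

Each visit's scan was compensated at γ ≈ 0.5–0.6 (the generator's
drusen shadows need mild correction). The target box's CCFD% is stable
from one year pre-onset to onset (Δ = 0.04, inside the 5% test–retest
band) and rises by ~15 points at the two post-onset visits — the
marked changes the MDC rule is built to detect. Truth for the same box is
available from `truth_box_ccfd(case$truth, res$grid, visit)` to verify
recovery.

The `analysis/` scripts run the same workflow as a small study:
`01_simulate.R` (6 null + 6 effect eyes written as TIFF/PNG),
`02_quantify.R` (per-case maps and box tables), `03_track_mdc.R`
(target series vs the MDC), `04_group_stats.R` (the four category-level
contrast tables). Outputs land under `results/`.

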