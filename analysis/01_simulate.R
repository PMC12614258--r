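#!/usr/bin/env Rscript
# Simulate the longitudinal study cohort: synthetic 4-visit SS-OCTA eyes
# with known ground truth, in three arms:
#   - null:   constant deficit fraction across visits (test-retest arm)
#   - effect: CC loss appearing near the lesion after hyperTD onset
# Writes each case's slabs and masks plus the scenario configs under
# results/cases/ so later steps (and an external reader) can re-load
# them from files.

suppressMessages(library(ccfdgrid))

out_root <- "results/cases"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

n_null <- 6L
n_effect <- 6L

write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in seq_along(case$visits)) {
    vr <- case$visits[[v]]
    pre <- file.path(dir, sprintf("visit%d", vr$visit_index))
    write_slab(vr$cc_flow, paste0(pre, "_cc_flow.tif"))
    write_slab(vr$cc_structure, paste0(pre, "_cc_structure.tif"))
    write_slab(vr$subrpe_structure, paste0(pre, "_subrpe_structure.tif"))
    write_slab(vr$vasculature, paste0(pre, "_vasculature.tif"))
    write_mask(vr$exclusion_mask, paste0(pre, "_exclusion_mask.png"))
    write_mask(vr$hypertd_mask, paste0(pre, "_hypertd_mask.png"))
  }
}

manifest <- list()
for (i in seq_len(n_null)) {
  p <- scenario_params(rng_seed = 100L + i)
  case <- generate_case(p)
  dir <- file.path(out_root, sprintf("null_%02d", i))
  write_case(case, dir)
  manifest[[basename(dir)]] <- list(arm = "null", rng_seed = p$rng_seed,
                                    patient_id = p$patient_id)
}
for (i in seq_len(n_effect)) {
  p <- scenario_params(deficit_fraction_post = 0.25, rng_seed = 200L + i)
  case <- generate_case(p)
  dir <- file.path(out_root, sprintf("effect_%02d", i))
  write_case(case, dir)
  manifest[[basename(dir)]] <- list(arm = "effect", rng_seed = p$rng_seed,
                                    patient_id = p$patient_id,
                                    deficit_fraction_post = 0.25)
}
write_run_metadata(manifest, file.path(out_root, "manifest.json"))
cat(sprintf("Simulated %d cases under %s\n", n_null + n_effect, out_root))
cat("Slabs are 16-bit TIFF, masks 8-bit PNG; every case has 4 visits\n")
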