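# Shared fixtures, built in code.

tiny_enface <- function(px, slab = "cc_flow", spacing = 12) {
  enface_image(px, spacing_um = spacing, slab_name = slab)
}

tiny_mask <- function(px, kind = "exclusion") mask_image(px, kind = kind)

empty_mask <- function(n, m = n, kind = "exclusion") {
  mask_image(matrix(FALSE, n, m), kind = kind)
}

# One default-scenario case plus its pipeline result, computed once per
# test run (several tests inspect different aspects of the same run).
.case_cache <- new.env(parent = emptyenv())
cached_case <- function() {
  if (is.null(.case_cache$case)) {
    .case_cache$case <- generate_case(scenario_params(rng_seed = 101L))
    .case_cache$res <- run_case(.case_cache$case$visits, ccfd_config())
  }
  list(case = .case_cache$case, res = .case_cache$res)
}

# Scenario helpers: the three study arms exercised by the tests.
scenario_null <- function(seed) scenario_params(rng_seed = seed)

scenario_clean <- function(seed) {
  scenario_params(drusen_depth = 1, flow_noise_sd = 0, n_drusen = 0L,
                  illum_field_sd = 0, rng_seed = seed)
}

scenario_effect <- function(seed) {
  scenario_params(deficit_fraction_post = 0.25, rng_seed = seed)
}
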