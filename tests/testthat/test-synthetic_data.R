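test_that("the generator is deterministic given its seed", {
  a <- generate_case(scenario_params(rng_seed = 5L))
  b <- generate_case(scenario_params(rng_seed = 5L))
  expect_identical(a$visits[[2]]$cc_flow$pixels, b$visits[[2]]$cc_flow$pixels)
  expect_identical(a$truth$deficit_mask, b$truth$deficit_mask)
  c <- generate_case(scenario_params(rng_seed = 6L))
  expect_false(identical(a$visits[[1]]$cc_flow$pixels,
                         c$visits[[1]]$cc_flow$pixels))
})

test_that("parameter validation rejects impossible scenarios", {
  expect_error(scenario_params(hypertd_radius_by_visit_um = c(0, 100, 150, 200)),
               "GLD")
  expect_error(scenario_params(deficit_fraction_pre = 1.2))
  expect_error(scenario_params(hypertd_radius_by_visit_um = c(0, 125, 150, 3000)),
               "bounds")
  # fraction beyond the hard-core disc packing limit fails at rendering
  expect_error(generate_case(scenario_params(deficit_fraction_pre = 0.5)),
               "packing")
})

test_that("lesion timeline matches the visit design", {
  case <- cached_case()$case
  expect_false(any(case$visits[[1]]$hypertd_mask$pixels))  # pre-onset
  for (v in 2:4) expect_true(any(case$visits[[v]]$hypertd_mask$pixels))
  # onset GLD from default 150-um radius: 25 px at 12 um/px = 300 um
  idx <- which(case$truth$hypertd_mask[[2]], arr.ind = TRUE)
  gld_px <- max(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1L
  expect_gte(gld_px * 12, 250)
  # lesion grows
  areas <- vapply(case$truth$hypertd_mask, sum, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("clean zero-deficit scans have no dark pixels outside lesions", {
  p <- scenario_params(deficit_fraction_pre = 0, deficit_fraction_post = 0,
                       drusen_depth = 1, flow_noise_sd = 0, n_drusen = 0L,
                       n_hypotd = 0L, vignette_px = 0L, rng_seed = 2L)
  case <- generate_case(p)
  flow <- case$visits[[1]]$cc_flow$pixels
  expect_true(all(flow >= 0.5 * p$baseline_flow_mean))
})

test_that("rendered deficit fraction matches the target within 1 point", {
  for (seed in c(1L, 9L, 33L)) {
    p <- scenario_params(rng_seed = seed)
    case <- generate_case(p)
    # interior of the field: the disc process stays clear of crop edges
    ix <- 41:460
    d <- case$truth$deficit_mask[[1]][ix, ix]
    excl <- case$truth$hypotd_mask[ix, ix]
    frac <- 100 * sum(d & !excl) / sum(!excl)
    expect_lt(abs(frac - 100 * p$deficit_fraction_pre), 1.0)
  }
})

test_that("stored true shift aligns each visit's vasculature to the reference", {
  case <- cached_case()$case
  ref <- case$visits[[4]]$vasculature$pixels
  for (v in 1:3) {
    t_v <- case$truth$true_shift[[v]]
    moved <- ccfdgrid:::translate_fill(case$visits[[v]]$vasculature$pixels,
                                       t_v[1], t_v[2], fill = NA_real_)
    interior <- !is.na(moved)
    expect_identical(moved[interior], ref[interior])
    expect_gt(mean(interior), 0.9)
  }
})

test_that("truth_box_ccfd reports the constructed per-box percentages", {
  p <- scenario_params(n_hypotd = 0L, rng_seed = 4L)
  case <- generate_case(p)
  grid <- tile_grid(c(500L, 500L), c(151L, 151L), ccfd_config())
  tr <- truth_box_ccfd(case$truth, grid, visit_index = 0L)
  # oracle: count mask pixels per box directly
  d <- case$truth$deficit_mask[[1]]
  oracle <- vapply(seq_len(nrow(grid$boxes)), function(i) {
    r <- grid$boxes$row0[i]:(grid$boxes$row0[i] + 73)
    cl <- grid$boxes$col0[i]:(grid$boxes$col0[i] + 73)
    100 * sum(d[r, cl]) / (74 * 74)
  }, numeric(1))
  expect_equal(unname(tr), oracle, tolerance = 1e-12)
  # interior boxes sample the uniform 10%-deficit field: disc-process
  # granularity gives each box a ~1.3-point sd, the mean sits near 10
  interior <- grid$boxes$row0 >= 40 & grid$boxes$col0 >= 40 &
    grid$boxes$row0 + 73 <= 460 & grid$boxes$col0 + 73 <= 460
  expect_gt(sum(interior), 5)
  expect_lt(abs(mean(tr[interior]) - 10), 1)

  # fully-deficit and fully-excluded boxes, built directly
  truth2 <- case$truth
  truth2$deficit_mask[[1]][1:100, 1:100] <- TRUE
  truth2$hypotd_mask[101:200, 1:100] <- TRUE
  g2 <- tile_grid(c(500L, 500L), c(1L, 1L),
                  ccfd_config(box_px = 100L))
  tr2 <- truth_box_ccfd(truth2, g2, 0L)
  b1 <- g2$boxes$box_id[g2$boxes$row0 == 1 & g2$boxes$col0 == 1]
  b2 <- g2$boxes$box_id[g2$boxes$row0 == 101 & g2$boxes$col0 == 1]
  expect_equal(unname(tr2[as.character(b1)]), 100)
  expect_true(is.na(tr2[as.character(b2)]))  # all pixels excluded
})

test_that("speckle option plants only sub-resolution deficits", {
  p <- scenario_params(speckle = TRUE, flow_noise_sd = 0, drusen_depth = 1,
                       n_drusen = 0L, deficit_fraction_pre = 0,
                       deficit_fraction_post = 0, n_hypotd = 0L,
                       vignette_px = 0L, illum_field_sd = 0, rng_seed = 8L)
  case <- generate_case(p)
  flow <- case$visits[[1]]$cc_flow$pixels
  # speckle pixels sit at the deficit decorrelation floor
  expect_gt(sum(flow == p$deficit_contrast * p$baseline_flow_mean), 0)
  expect_false(any(case$truth$deficit_mask[[1]]))  # but not in the truth
})
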