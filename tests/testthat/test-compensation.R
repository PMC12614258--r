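test_that("reference smoothing matches a direct convolution oracle", {
  set.seed(11)
  px <- matrix(runif(31 * 31, 0, 200), 31, 31)
  cfg <- ccfd_config()
  sm <- smooth_reference(tiny_enface(px, "subrpe_structure"), cfg)
  k <- ccfdgrid:::gaussian_kernel(cfg$smooth_kernel_px, cfg$smooth_sigma)
  oracle <- naive_convolve_reflect(px, k)
  expect_equal(sm$pixels, pmax(oracle, 1e-3 * max(oracle)),
               tolerance = 1e-8)
})

test_that("smoothing preserves constants, mass, and floors zero rasters", {
  cfg <- ccfd_config()
  const <- smooth_reference(tiny_enface(matrix(7, 20, 20),
                                        "subrpe_structure"), cfg)
  expect_equal(const$pixels, matrix(7, 20, 20), tolerance = 1e-10)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- smooth_reference(tiny_enface(imp, "subrpe_structure"), cfg)
  # blur is mass-preserving (reflective borders); pixels outside the
  # kernel support sit at the epsilon floor and are not blur mass
  expect_equal(sum(sm$pixels[sm$pixels > 1e-3]), 1, tolerance = 1e-6)

  z <- smooth_reference(tiny_enface(matrix(0, 20, 20),
                                    "subrpe_structure"), cfg)
  expect_true(all(z$pixels > 0))  # epsilon floor
})

test_that("compensation factor follows N^(-gamma) with mask protection", {
  # reference: body 100 (the P99 level), one pixel at 50 -> N = 0.5
  ref <- matrix(100, 20, 20); ref[5, 5] <- 50; ref[6, 6] <- 50
  flow <- matrix(10, 20, 20)
  struct <- matrix(40, 20, 20)
  flow[20, 20] <- 100  # sets the dynamic-range ceiling
  comp_mask <- matrix(FALSE, 20, 20); comp_mask[6, 6] <- TRUE
  args <- list(tiny_enface(flow), tiny_enface(struct, "cc_structure"),
               tiny_enface(ref, "subrpe_structure"),
               tiny_mask(comp_mask, "hypertd"))

  out0 <- do.call(compensate, c(args, gamma = 0))
  expect_identical(out0$flow$pixels, flow)     # gamma 0: exact identity

  out1 <- do.call(compensate, c(args, gamma = 1))
  expect_equal(out1$flow$pixels[5, 5], 20)     # N=0.5, factor 2
  expect_equal(out1$flow$pixels[6, 6], 10)     # masked: unchanged
  expect_equal(out1$flow$pixels[1, 1], 10)     # N=1: unchanged

  out3 <- do.call(compensate, c(args, gamma = 3))
  expect_equal(out3$flow$pixels[5, 5], 80)     # factor 8
  expect_equal(out3$flow$pixels[6, 6], 10)     # still masked
  expect_error(do.call(compensate, c(args, gamma = -1)), "gamma")
})

test_that("outputs are clipped at the input ceiling and masks are bit-stable", {
  set.seed(21)
  n <- 60
  ref <- matrix(runif(n^2, 20, 100), n, n)
  flow <- matrix(runif(n^2, 0, 200), n, n)
  struct <- matrix(runif(n^2, 0, 180), n, n)
  comp_mask <- matrix(runif(n^2) < 0.2, n, n)
  out <- compensate(tiny_enface(flow), tiny_enface(struct, "cc_structure"),
                    tiny_enface(ref, "subrpe_structure"),
                    tiny_mask(comp_mask, "hypertd"), gamma = 2.5)
  expect_lte(max(out$flow$pixels), max(flow))
  expect_lte(max(out$structure$pixels), max(struct))
  expect_identical(out$flow$pixels[comp_mask], flow[comp_mask])
  expect_identical(out$structure$pixels[comp_mask], struct[comp_mask])
})

test_that("gamma optimization matches a fine-grid brute force on synthetic attenuation", {
  set.seed(31)
  n <- 120
  # attenuation field A, structure = A * S0 + noise, reference recovers A
  rows <- matrix(1:n, n, n); cols <- t(rows)
  A <- 1 - 0.4 * exp(-((rows - 40)^2 + (cols - 60)^2) / (2 * 15^2))
  A <- A * (1 - 0.35 * exp(-((rows - 90)^2 + (cols - 30)^2) / (2 * 12^2)))
  struct <- A * 150 + rnorm(n^2, 0, 4)
  struct <- pmax(struct, 0)
  ref <- A * 120
  cfg <- ccfd_config()
  res <- optimize_gamma(tiny_enface(struct, "cc_structure"),
                        tiny_enface(ref, "subrpe_structure"),
                        empty_mask(n, kind = "hypertd"),
                        empty_mask(n), cfg)
  fine <- gamma_bruteforce(struct, ref, matrix(TRUE, n, n),
                           seq(0, 5, by = 0.01))
  expect_lt(abs(res$gamma_star - fine), 0.3)
  expect_equal(unname(res$objective_curve[
    which(cfg$gamma_grid == res$gamma_star)]),
    min(res$objective_curve))
})

test_that("gamma tie-breaks, singleton grids, and eligibility preconditions", {
  n <- 30
  struct <- matrix(rep(c(10, 30), length.out = n^2), n, n)
  flat_ref <- matrix(80, n, n)
  res <- optimize_gamma(tiny_enface(struct, "cc_structure"),
                        tiny_enface(flat_ref, "subrpe_structure"),
                        empty_mask(n, kind = "hypertd"), empty_mask(n))
  expect_equal(res$gamma_star, 0)  # all objectives equal -> smallest gamma

  res1 <- optimize_gamma(tiny_enface(struct, "cc_structure"),
                         tiny_enface(flat_ref, "subrpe_structure"),
                         empty_mask(n, kind = "hypertd"), empty_mask(n),
                         ccfd_config(gamma_grid = 1.0))
  expect_equal(res1$gamma_star, 1.0)

  excl <- mask_image(matrix(TRUE, n, n), "exclusion")
  excl$pixels[1:5, 1:5] <- FALSE   # only 25 eligible pixels
  expect_error(
    optimize_gamma(tiny_enface(struct, "cc_structure"),
                   tiny_enface(flat_ref, "subrpe_structure"),
                   empty_mask(n, kind = "hypertd"), excl),
    "unquantifiable")
})

test_that("compensation at gamma* improves structure homogeneity and CCFD accuracy", {
  cc <- cached_case()
  case <- cc$case; res <- cc$res
  cfg <- ccfd_config()
  v <- case$visits[[1]]
  low_sig <- low_signal_mask(v$cc_structure, cfg)
  ref <- smooth_reference(v$subrpe_structure, cfg)
  opt <- optimize_gamma(v$cc_structure, ref, v$hypertd_mask,
                        v$exclusion_mask, cfg, low_sig = low_sig)
  expect_gt(opt$gamma_star, 0)
  # sd at gamma* is below the uncompensated sd (gamma = 0 entry)
  expect_lt(min(opt$objective_curve), opt$objective_curve[["0.0"]])

  # with compensation, measured CCFD% tracks truth; without, deficits
  # are overcalled in drusen shadows
  grid <- res$grid
  tr <- truth_box_ccfd(case$truth, grid, 0L)
  meas <- res$table[res$table$visit_index == 0 & res$table$included, ]
  err_comp <- meas$ccfd_pct - tr[as.character(meas$box_id)]
  expect_lt(max(abs(err_comp)), 3)

  comp0 <- compensate(v$cc_flow, v$cc_structure, ref, v$hypertd_mask, 0)
  fcm0 <- fcm_threshold(comp0$flow, valid_mask = v$exclusion_mask, cfg)
  map0 <- remove_small_deficits(
    binarize(comp0$flow, fcm0, v$exclusion_mask), cfg)
  t0 <- ccfdgrid:::translate_fill(map0$state,
                                  case$truth$true_shift[[1]][1],
                                  case$truth$true_shift[[1]][2],
                                  fill = 2L)
  storage.mode(t0) <- "integer"
  map0r <- ccfd_map(t0, spacing_um = 12)
  ls0 <- apply_transform(low_sig, ccfd_transform(
    case$truth$true_shift[[1]][1], case$truth$true_shift[[1]][2]))
  err_uncomp <- vapply(seq_len(nrow(grid$boxes)), function(i) {
    b <- c(grid$boxes$row0[i], grid$boxes$col0[i])
    o <- box_ccfd(map0r, b, low_sig = ls0, config = cfg)
    o$ccfd_pct - tr[as.character(grid$boxes$box_id[i])]
  }, numeric(1))
  # uncompensated bias exceeds the compensated error in shadowed boxes
  expect_gt(max(err_uncomp, na.rm = TRUE), max(abs(err_comp)))
  expect_gt(mean(err_uncomp, na.rm = TRUE), 0)
})
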