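test_that("target box centers on the annotation centroid with clamping", {
  cfg <- ccfd_config()
  ann <- matrix(FALSE, 500, 500)
  ann[249:253, 249:253] <- TRUE   # centroid (251, 251)
  tb <- make_target_box(tiny_mask(ann, "hypertd"), cfg)
  expect_identical(tb, c(214L, 214L))  # 251 - 74 %/% 2

  single <- matrix(FALSE, 500, 500); single[100, 100] <- TRUE
  expect_identical(make_target_box(tiny_mask(single, "hypertd"), cfg),
                   c(63L, 63L))

  corner <- matrix(FALSE, 500, 500); corner[10, 10] <- TRUE
  expect_identical(make_target_box(tiny_mask(corner, "hypertd"), cfg),
                   c(1L, 1L))           # clamped inside the raster

  expect_error(make_target_box(empty_mask(500, kind = "hypertd"), cfg),
               "empty")
})

test_that("grid tiling accommodates only complete boxes", {
  cfg <- ccfd_config()
  g0 <- tile_grid(c(500L, 500L), c(1L, 1L), cfg)
  expect_identical(nrow(g0$boxes), 36L)          # floor(500/74)^2
  g52 <- tile_grid(c(500L, 500L), c(53L, 53L), cfg)  # offset 52 px
  expect_identical(nrow(g52$boxes), 36L)         # floor(448/74) = 6
  g1 <- tile_grid(c(74L, 74L), c(1L, 1L), cfg)
  expect_identical(nrow(g1$boxes), 1L)

  # boxes partition a sub-rectangle: no overlaps, all within the raster
  cover <- matrix(0L, 500, 500)
  for (i in seq_len(nrow(g52$boxes))) {
    r <- g52$boxes$row0[i]; cl <- g52$boxes$col0[i]
    cover[r:(r + 73), cl:(cl + 73)] <- cover[r:(r + 73), cl:(cl + 73)] + 1L
  }
  expect_lte(max(cover), 1L)
  expect_identical(sum(cover), 36L * 74L * 74L)
  # target box is on the lattice
  expect_true(g52$target_box_id %in% g52$boxes$box_id)
})

test_that("box categories follow hyperTD overlap and lattice adjacency", {
  cfg <- ccfd_config()
  n <- 5 * 74L
  center <- (n - 74L) / 2 + 1L
  grid <- tile_grid(c(n, n), c(center, center), cfg)
  expect_identical(nrow(grid$boxes), 25L)
  hyper <- matrix(FALSE, n, n)
  hyper[center + 30, center + 30] <- TRUE   # inside the center box only
  cats <- classify_boxes(grid, list(tiny_mask(hyper, "hypertd")))
  tab <- table(factor(cats, levels = c("target", "nontarget_hypertd",
                                       "adjacent_background",
                                       "nonadjacent_background")))
  expect_identical(as.integer(tab),
                   c(1L, 0L, 8L, 16L))  # 5x5: center + ring + outside
  expect_identical(sum(tab), 25L)       # partition of all boxes

  # 3x3 grid, center-only lesion: everything else is adjacent
  n3 <- 3 * 74L
  g3 <- tile_grid(c(n3, n3), c(75L, 75L), cfg)
  h3 <- matrix(FALSE, n3, n3); h3[100, 100] <- TRUE
  c3 <- classify_boxes(g3, list(tiny_mask(h3, "hypertd")))
  expect_identical(sum(c3 == "target"), 1L)
  expect_identical(sum(c3 == "adjacent_background"), 8L)
  expect_identical(sum(c3 == "nonadjacent_background"), 0L)

  # lesion spillover into a neighbouring box makes it nontarget_hypertd
  hyper2 <- hyper
  hyper2[(center + 74L):(center + 80L), center + 30] <- TRUE
  cats2 <- classify_boxes(grid, list(tiny_mask(hyper2, "hypertd")))
  expect_identical(sum(cats2 == "nontarget_hypertd"), 1L)
  expect_identical(sum(cats2 == "target"), 1L)
})

test_that("low-signal mask thresholds 5 dB over the darkest-5% median", {
  n <- 40  # 1600 px
  px <- matrix(1000, n, n)
  px[1:2, 1:40] <- 10          # exactly 5% of pixels at the floor
  m <- low_signal_mask(tiny_enface(px, "cc_structure"))
  expect_identical(m$pixels, px == 10)   # 10 < 31.6 <= 1000

  px2 <- matrix(25, n, n); px2[1:2, 1:40] <- 10
  m2 <- low_signal_mask(tiny_enface(px2, "cc_structure"))
  expect_true(all(m2$pixels))            # body 25 < 31.6: masked too

  const <- low_signal_mask(tiny_enface(matrix(7, n, n), "cc_structure"))
  expect_true(all(const$pixels))         # c < c * 10^(1/2) always
})

test_that("box CCFD applies availability and the strict 25% rule", {
  cfg <- ccfd_config()
  b <- cfg$box_px
  st <- matrix(0L, 100, 100)
  st[1:37, 1:74] <- 1L                  # half the box is deficit
  map <- ccfd_map(st)
  o <- box_ccfd(map, c(1L, 1L), config = cfg)
  expect_equal(o$ccfd_pct, 50)
  expect_equal(o$valid_frac, 1)
  expect_true(o$included_visit)

  # exactly 25% unavailable: still included (strictly "more than 25%")
  in_box <- which(row(st) <= b & col(st) <= b)
  st2 <- matrix(0L, 100, 100)
  st2[in_box[seq_len(round(0.25 * b^2))]] <- 2L
  o2 <- box_ccfd(ccfd_map(st2), c(1L, 1L), config = cfg)
  expect_equal(o2$valid_frac, 0.75)
  expect_true(o2$included_visit)

  # 30% unavailable: excluded
  st3 <- matrix(0L, 100, 100)
  st3[in_box[seq_len(round(0.3 * b^2))]] <- 2L
  o3 <- box_ccfd(ccfd_map(st3), c(1L, 1L), config = cfg)
  expect_false(o3$included_visit)

  # invalid pixels leave both numerator and denominator
  st4 <- matrix(0L, 100, 100)
  st4[1:10, 1:74] <- 1L
  st4[11:20, 1:74] <- 2L
  o4 <- box_ccfd(ccfd_map(st4), c(1L, 1L), config = cfg)
  expect_equal(o4$ccfd_pct, 100 * 740 / (74^2 - 740))
  expect_error(box_ccfd(map, c(90L, 90L), config = cfg), "outside")

  # all pixels unavailable: missing percentage
  st5 <- matrix(2L, 100, 100)
  o5 <- box_ccfd(ccfd_map(st5), c(1L, 1L), config = cfg)
  expect_true(is.na(o5$ccfd_pct))
})

test_that("study-wide exclusion drops a box failing the rule at any visit", {
  cfg <- ccfd_config(box_px = 10L)
  good <- ccfd_map(matrix(0L, 20, 20))
  bad <- ccfd_map({
    st <- matrix(0L, 20, 20); st[1:6, 1:10] <- 2L; st
  })
  grid <- tile_grid(c(20L, 20L), c(1L, 1L), cfg)
  cats <- stats::setNames(rep("nonadjacent_background", 4),
                          grid$boxes$box_id)
  cats[grid$target_box_id] <- "target"
  tb <- box_table(list(good, good, bad, good), grid, cats, config = cfg)
  first_box <- tb[tb$box_id == 1L, ]
  expect_false(any(first_box$included))    # failed at visit 2 only
  expect_true(all(is.na(first_box$ccfd_pct)))
  other <- tb[tb$box_id == 4L, ]
  expect_true(all(other$included))
  expect_identical(nrow(tb), 16L)
})

test_that("grid overlay PNG marks box borders and the target box", {
  dir <- withr::local_tempdir()
  cfg <- ccfd_config(box_px = 10L)
  grid <- tile_grid(c(30L, 30L), c(11L, 11L), cfg)
  map <- ccfd_map(matrix(0L, 30, 30))
  path <- file.path(dir, "overlay.png")
  write_grid_overlay(map, grid, path)
  img <- png::readPNG(path)
  expect_equal(img[11, 11], 1)          # target box border, bright
  expect_equal(img[1, 5], 0.7, tolerance = 0.01)  # ordinary border
  expect_equal(img[5, 5], 0)            # interior stays flow-black
})

test_that("MDC flags changes strictly above 5 points in either direction", {
  # published workflow example: 8.8, 7.3, 25.6, 28.3
  flags <- mdc_change(c(8.8, 7.3, 25.6, 28.3))
  expect_identical(flags$marked_change, c(NA, FALSE, TRUE, TRUE))
  expect_equal(flags$delta, c(0, -1.5, 16.8, 19.5))

  expect_identical(mdc_change(c(10, 15))$marked_change[2], FALSE)  # = 5.0
  expect_identical(mdc_change(c(10, 4))$marked_change[2], TRUE)    # -6.0
  expect_error(mdc_change(c(NA, 10, 10, 10)), "baseline")
  expect_error(mdc_change(5), "two visits")
})
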