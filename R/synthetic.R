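#' Scenario parameters for the synthetic longitudinal generator
#'
#' Defines one simulated eye followed over four visits: one year before
#' hyperTD onset (visit 0), at onset (visit 1), and one and two years
#' after (visits 2, 3). Ground-truth flow-deficit fractions, drusen
#' attenuation, lesion growth, shadowing hypoTDs and inter-visit
#' translations are all known so every pipeline stage can be checked
#' against truth.
#'
#' @param shape_px Raster dimensions, default 500 x 500.
#' @param spacing_um Pixel spacing (um/px).
#' @param baseline_flow_mean Mean CC flow intensity where perfused.
#' @param flow_noise_sd SD of the Gaussian intensity noise at the
#'   baseline signal level, applied per visit to the flow and structure
#'   slabs. The noise is heteroscedastic, as OCT speckle is: the
#'   per-pixel sd scales with the clean signal
#'   (`sd(x) = flow_noise_sd * x / baseline_flow_mean + dark_noise_sd`)
#'   and the result is truncated at zero.
#' @param dark_noise_sd Detector noise sd where no signal is present.
#' @param structure_mean,subrpe_mean Mean intensities of the CC structure
#'   and sub-RPE structure slabs.
#' @param deficit_fraction_pre,deficit_fraction_post Ground-truth CCFD
#'   fraction inside the lesion neighborhood before (visits 0-1) and
#'   after (visits 2-3) the post-onset change; equal values give the null
#'   scenario. Outside the neighborhood the pre fraction applies
#'   throughout.
#' @param deficit_contrast Residual flow-signal fraction inside a
#'   deficit: OCTA deficits are decorrelation-signal floors, not true
#'   zeros, so deficit pixels carry `deficit_contrast * baseline`
#'   before noise.
#' @param illum_field_sd Standard deviation of a smooth multiplicative
#'   per-visit illumination field (fractional, applied to all OCT
#'   slabs); models the scan-to-scan illumination and bulk-motion
#'   variability that drives CCFD% test-retest error. 0 disables.
#' @param illum_scale_px Correlation scale of that field in pixels.
#' @param effect_radius_um Radius of the lesion neighborhood affected by
#'   the post-onset change.
#' @param n_drusen Number of drusen attenuation bumps.
#' @param drusen_depth Multiplicative attenuation at a bump center,
#'   in (0, 1]; 1 disables attenuation.
#' @param drusen_sigma_um Gaussian sigma of each bump.
#' @param hypertd_radius_by_visit_um Lesion radius per visit (visit 0
#'   must be 0; onset GLD = 2 * radius must reach 250 um).
#' @param n_hypotd Number of shadowing hypoTD lesions.
#' @param hypotd_radius_um HypoTD radius.
#' @param visit_shifts List of four `c(dy, dx)` integer translations (the
#'   anatomy-to-image displacement per visit); the final visit is the
#'   registration reference.
#' @param vignette_px Width of the instrument-frame field vignette band
#'   at the scan margin, where beam roll-off drops the OCT signal of the
#'   CC and sub-RPE slabs to the noise floor; this gives the scan a
#'   genuine background population for the 5-dB low-signal rule. The
#'   retinal vasculature slab is unaffected. 0 disables.
#' @param vignette_depth Multiplicative signal factor inside the band.
#' @param speckle Add sub-resolution (single-pixel) false deficits to
#'   exercise the 24-um size filter.
#' @param patient_id,eye_id Identifiers stamped on the visit records;
#'   default derives them from the seed so pooled studies keep cases
#'   distinct.
#' @param rng_seed Integer seed; the generated case is a deterministic
#'   function of the parameters.
#'
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(shape_px = c(500L, 500L),
                            spacing_um = 12,
                            baseline_flow_mean = 180,
                            flow_noise_sd = 20,
                            dark_noise_sd = 1,
                            structure_mean = 160,
                            subrpe_mean = 120,
                            deficit_fraction_pre = 0.10,
                            deficit_fraction_post = 0.10,
                            deficit_contrast = 0.4,
                            illum_field_sd = 0.05,
                            illum_scale_px = 25L,
                            effect_radius_um = 1300,
                            n_drusen = 15L,
                            drusen_depth = 0.55,
                            drusen_sigma_um = 300,
                            hypertd_radius_by_visit_um = c(0, 150, 220, 300),
                            n_hypotd = 2L,
                            hypotd_radius_um = 60,
                            visit_shifts = list(c(8L, -5L), c(-4L, 7L),
                                                c(3L, 2L), c(0L, 0L)),
                            vignette_px = 25L,
                            vignette_depth = 0.05,
                            speckle = FALSE,
                            patient_id = NULL,
                            eye_id = NULL,
                            rng_seed = 1L) {
  stopifnot(length(shape_px) == 2, all(shape_px >= 148),
            spacing_um > 0, baseline_flow_mean > 0, flow_noise_sd >= 0,
            deficit_fraction_pre >= 0, deficit_fraction_pre <= 1,
            deficit_fraction_post >= 0, deficit_fraction_post <= 1,
            deficit_contrast >= 0, deficit_contrast < 1,
            illum_field_sd >= 0, illum_scale_px >= 2,
            drusen_depth > 0, drusen_depth <= 1,
            length(hypertd_radius_by_visit_um) == 4,
            hypertd_radius_by_visit_um[1] == 0,
            length(visit_shifts) == 4)
  if (2 * hypertd_radius_by_visit_um[2] < 250)
    stop("onset hyperTD GLD must be at least 250 um")
  max_r_px <- max(hypertd_radius_by_visit_um) / spacing_um
  if (2 * max_r_px > min(shape_px) / 2)
    stop("lesion radius exceeds image bounds")
  if (is.null(patient_id)) patient_id <- paste0("pt", rng_seed)
  if (is.null(eye_id)) eye_id <- paste0("eye", rng_seed)
  structure(as.list(environment()), class = "scenario_params")
}

# Restore the caller's RNG state on exit.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic 4-visit case
#'
#' Renders anatomy once on a padded canvas (vessel tree, drusen
#' attenuation field, flow-deficit disc process, growing hyperTD,
#' hypoTD shadows) and crops each visit's rasters at its known
#' translation, so registered visits are pixel-identical in their
#' interiors. CC flow is `baseline * attenuation * (1 - deficit)` plus
#' truncated Gaussian noise; structure slabs share the attenuation
#' field; the hyperTD is rendered as elevated sub-RPE brightness with no
#' attenuation over the lesion; hypoTDs null the signal in all slabs and
#' are copied into the exclusion mask.
#'
#' @param params A [scenario_params()].
#' @return A list with `visits` (list of four [visit_record()]s) and
#'   `truth` (class `synthetic_truth`: reference-frame noise-free
#'   `deficit_mask`, `attenuation_field`, `hypertd_mask`, `hypotd_mask`,
#'   `comp_mask` per visit, plus `true_shift` per visit and the lesion
#'   center).
#' @export
generate_case <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  with_seed(params$rng_seed, generate_case_impl(params))
}

generate_case_impl <- function(p) {
  n <- p$shape_px[1]; m <- p$shape_px[2]
  sp <- p$spacing_um
  shifts <- lapply(p$visit_shifts, as.integer)
  P <- max(1L, max(vapply(shifts, function(s) max(abs(s)), integer(1))))
  N <- n + 2L * P; M <- m + 2L * P

  # --- static anatomy on the canvas ------------------------------------
  vessels <- render_vessel_tree(N, M)
  cy <- round(N / 2 + runif(1, -20, 20))
  cx <- round(M / 2 + runif(1, -20, 20))
  drusen <- render_attenuation(N, M, p$n_drusen, p$drusen_depth,
                               p$drusen_sigma_um / sp,
                               avoid = c(cy, cx),
                               avoid_r = max(p$hypertd_radius_by_visit_um) / sp)
  hypotd <- render_discs(N, M, p$n_hypotd, p$hypotd_radius_um / sp,
                         avoid = c(cy, cx),
                         avoid_r = (max(p$hypertd_radius_by_visit_um) +
                                    p$effect_radius_um) / sp + 10)

  # deficit disc process: jittered hard-core lattice, disc radius 2 px
  # (48-um diameter, safely above the 24-um filter)
  disc_r <- 2L; pitch <- 6L
  disc_area <- sum(outer((-disc_r):disc_r, (-disc_r):disc_r,
                         function(a, b) a^2 + b^2) <= disc_r^2)
  cell_area <- pitch^2
  p_pre <- p$deficit_fraction_pre * cell_area / disc_area
  p_post <- p$deficit_fraction_post * cell_area / disc_area
  if (max(p_pre, p_post) > 1)
    stop("deficit fraction exceeds the lattice packing limit of ",
         round(disc_area / cell_area, 2))
  sites <- lattice_sites(N, M, pitch)
  # keep discs clear of every visit's crop window so no component is
  # clipped below the size-filter scale at a field edge
  smat <- do.call(rbind, shifts)
  lo <- 1L + P + apply(smat, 2, max) + disc_r
  hi <- c(n, m) + P + apply(smat, 2, min) - disc_r
  keep_site <- sites[, 1] >= lo[1] & sites[, 1] <= hi[1] &
    sites[, 2] >= lo[2] & sites[, 2] <= hi[2]
  sites <- sites[keep_site, , drop = FALSE]
  keep_base <- runif(nrow(sites)) < p_pre
  base_mask <- discs_at(N, M, sites[keep_base, , drop = FALSE], disc_r)
  in_nbhd <- (sites[, 1] - cy)^2 + (sites[, 2] - cx)^2 <=
    (p$effect_radius_um / sp)^2
  extra_mask <- NULL
  if (p_post > p_pre) {
    q <- (p_post - p_pre) / (1 - p_pre)
    keep_extra <- !keep_base & in_nbhd & (runif(nrow(sites)) < q)
    extra_mask <- discs_at(N, M, sites[keep_extra, , drop = FALSE], disc_r)
  }
  speckle_mask <- NULL
  if (isTRUE(p$speckle)) {
    idx <- cbind(sample.int(N, 400L, replace = TRUE),
                 sample.int(M, 400L, replace = TRUE))
    speckle_mask <- matrix(FALSE, N, M)
    speckle_mask[idx] <- TRUE
  }

  # lesion discs per visit
  hyper_by_visit <- lapply(p$hypertd_radius_by_visit_um / sp, function(r) {
    if (r <= 0) matrix(FALSE, N, M)
    else disc_mask(N, M, cy, cx, r)
  })
  deficit_by_visit <- lapply(0:3, function(v) {
    d <- base_mask
    if (!is.null(extra_mask) && v >= 2) d <- d | extra_mask
    d
  })

  # --- per-visit rendering ---------------------------------------------
  ref_shift <- shifts[[4]]
  crop <- function(X, s) {
    X[(1 + P + s[1]):(n + P + s[1]), (1 + P + s[2]):(m + P + s[2]),
      drop = FALSE]
  }
  crop_ref <- function(X) crop(X, ref_shift)

  visits <- vector("list", 4)
  for (v in 0:3) {
    hyper <- hyper_by_visit[[v + 1]]
    att <- drusen
    att[hyper] <- 1                      # no attenuation over the lesion
    deficit <- deficit_by_visit[[v + 1]]
    flow_clean <- p$baseline_flow_mean * att *
      (1 - (1 - p$deficit_contrast) * deficit)
    if (!is.null(speckle_mask))
      flow_clean[speckle_mask] <- p$deficit_contrast *
        p$baseline_flow_mean * att[speckle_mask]
    struct_clean <- p$structure_mean * att
    sub_att <- drusen; sub_att[hyper] <- 1
    subrpe_clean <- p$subrpe_mean * sub_att
    subrpe_clean[hyper] <- p$subrpe_mean * 2   # elevated lesion brightness
    for (nm in c("flow_clean", "struct_clean", "subrpe_clean")) {
      x <- get(nm); x[hypotd] <- x[hypotd] * 0.02; assign(nm, x)
    }
    s <- shifts[[v + 1]]
    w <- p$vignette_px
    illum <- if (p$illum_field_sd > 0)
      1 + smooth_noise_field(n, m, p$illum_scale_px) * p$illum_field_sd
    else NULL
    noisy <- function(X) {
      Xc <- crop(X, s)
      if (w > 0) {   # instrument-frame beam roll-off at the scan margin
        band <- matrix(FALSE, n, m)
        band[c(1:w, (n - w + 1):n), ] <- TRUE
        band[, c(1:w, (m - w + 1):m)] <- TRUE
        Xc[band] <- Xc[band] * p$vignette_depth
      }
      if (!is.null(illum)) Xc <- pmax(Xc * illum, 0)
      if (p$flow_noise_sd > 0) {
        sd_px <- p$flow_noise_sd * Xc / p$baseline_flow_mean +
          p$dark_noise_sd
        Xc <- pmax(Xc + rnorm(length(Xc), 0, sd_px), 0)
      }
      Xc
    }
    visits[[v + 1]] <- visit_record(
      visit_index = v,
      cc_flow = enface_image(noisy(flow_clean), sp, "cc_flow"),
      cc_structure = enface_image(noisy(struct_clean), sp, "cc_structure"),
      subrpe_structure = enface_image(noisy(subrpe_clean), sp,
                                      "subrpe_structure"),
      vasculature = enface_image(crop(vessels, s), sp, "vasculature"),
      exclusion_mask = mask_image(crop(hypotd, s), "exclusion"),
      hypertd_mask = mask_image(crop(hyper, s), "hypertd"),
      eye_id = p$eye_id, patient_id = p$patient_id)
  }

  truth <- structure(list(
    deficit_mask = lapply(deficit_by_visit, crop_ref),
    attenuation_field = crop_ref(drusen),
    hypertd_mask = lapply(hyper_by_visit, crop_ref),
    hypotd_mask = crop_ref(hypotd),
    true_shift = lapply(shifts, function(s) s - ref_shift),
    lesion_center_ref = c(cy - P - ref_shift[1], cx - P - ref_shift[2]),
    params = p
  ), class = "synthetic_truth")
  list(visits = visits, truth = truth)
}

# Smooth unit-variance noise field: white noise on a coarse grid,
# bilinearly upsampled to the image size.
smooth_noise_field <- function(n, m, scale_px) {
  nc <- ceiling(n / scale_px) + 1L
  mc <- ceiling(m / scale_px) + 1L
  coarse <- matrix(rnorm(nc * mc), nc, mc)
  gy <- seq(1, nc, length.out = n)
  gx <- seq(1, mc, length.out = m)
  y0 <- pmin(floor(gy), nc - 1L); x0 <- pmin(floor(gx), mc - 1L)
  fy <- gy - y0; fx <- gx - x0
  a <- coarse[cbind(rep(y0, m), rep(x0, each = n))]
  b <- coarse[cbind(rep(y0 + 1, m), rep(x0, each = n))]
  cc <- coarse[cbind(rep(y0, m), rep(x0 + 1, each = n))]
  d <- coarse[cbind(rep(y0 + 1, m), rep(x0 + 1, each = n))]
  wy <- rep(fy, m); wx <- rep(fx, each = n)
  field <- (1 - wy) * (1 - wx) * a + wy * (1 - wx) * b +
    (1 - wy) * wx * cc + wy * wx * d
  matrix(field / stats::sd(field), n, m)
}

# Jittered lattice site centers (hard-core: jitter keeps discs disjoint).
lattice_sites <- function(N, M, pitch) {
  gy <- seq.int(pitch %/% 2 + 1L, N - pitch %/% 2, by = pitch)
  gx <- seq.int(pitch %/% 2 + 1L, M - pitch %/% 2, by = pitch)
  g <- as.matrix(expand.grid(gy, gx))
  jitter <- matrix(sample(c(-1L, 0L, 1L), 2L * nrow(g), replace = TRUE),
                   ncol = 2)
  g + jitter
}

# Stamp discs of radius r at the given centers.
discs_at <- function(N, M, centers, r) {
  out <- matrix(FALSE, N, M)
  if (nrow(centers) == 0) return(out)
  offs <- as.matrix(expand.grid((-r):r, (-r):r))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= r^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    ry <- centers[, 1] + offs[k, 1]; rx <- centers[, 2] + offs[k, 2]
    ok <- ry >= 1 & ry <= N & rx >= 1 & rx <= M
    out[cbind(ry[ok], rx[ok])] <- TRUE
  }
  out
}

# Boolean disc of radius r centered at (cy, cx).
disc_mask <- function(N, M, cy, cx, r) {
  outer((1:N) - cy, (1:M) - cx, function(a, b) a^2 + b^2 <= r^2)
}

# Product-of-Gaussian-bumps attenuation field in (0, 1]. Drusen are
# discrete lesions: centers keep a hard-core distance of 2.2 sigma so
# bumps do not stack into unphysically deep shadows.
render_attenuation <- function(N, M, n_drusen, depth, sigma_px,
                               avoid, avoid_r) {
  att <- matrix(1, N, M)
  if (n_drusen == 0 || depth >= 1) return(att)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  rows <- matrix(1:N, N, M); cols <- matrix(1:M, N, M, byrow = TRUE)
  while (nrow(centers) < n_drusen && tries < n_drusen * 50L) {
    tries <- tries + 1L
    cy <- runif(1, 1, N); cx <- runif(1, 1, M)
    if ((cy - avoid[1])^2 + (cx - avoid[2])^2 < (avoid_r + sigma_px)^2)
      next
    if (nrow(centers) > 0 &&
        min((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) <
          (2.2 * sigma_px)^2)
      next
    d2 <- (rows - cy)^2 + (cols - cx)^2
    att <- att * (1 - (1 - depth) * exp(-d2 / (2 * sigma_px^2)))
    centers <- rbind(centers, c(cy, cx))
  }
  att
}

# Union of n random discs avoiding a protected region.
render_discs <- function(N, M, n, r, avoid, avoid_r) {
  out <- matrix(FALSE, N, M)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < n * 50L + 50L) {
    tries <- tries + 1L
    cy <- round(runif(1, r + 1, N - r)); cx <- round(runif(1, r + 1, M - r))
    if ((cy - avoid[1])^2 + (cx - avoid[2])^2 < (avoid_r + r)^2) next
    out <- out | disc_mask(N, M, cy, cx, r)
    placed <- placed + 1L
  }
  out
}

# Random branching vessel tree: bright ridges over a dark background.
render_vessel_tree <- function(N, M) {
  n_seeds <- 6L
  max_walkers <- 64L
  ys <- runif(n_seeds, 0.2 * N, 0.8 * N)
  xs <- rep(c(2, M - 1), length.out = n_seeds)
  ang <- ifelse(xs < M / 2, 0, pi) + runif(n_seeds, -0.3, 0.3)
  y <- ys; x <- xs; a <- ang
  centerline <- matrix(FALSE, N, M)
  for (step in 1:400) {
    if (!length(y)) break
    a <- a + rnorm(length(a), 0, 0.12)
    y <- y + 2.2 * sin(a); x <- x + 2.2 * cos(a)
    ok <- y >= 2 & y <= N - 1 & x >= 2 & x <= M - 1
    y <- y[ok]; x <- x[ok]; a <- a[ok]
    if (!length(y)) break
    iy <- round(y); ix <- round(x)
    centerline[cbind(iy, ix)] <- TRUE
    if (length(y) < max_walkers) {
      b <- runif(length(y)) < 0.02
      if (any(b)) {
        sgn <- sample(c(-1, 1), sum(b), replace = TRUE)
        y <- c(y, y[b]); x <- c(x, x[b])
        a <- c(a, a[b] + sgn * runif(sum(b), 0.4, 0.9))
      }
    }
  }
  thick <- EBImage::dilate(centerline * 1, EBImage::makeBrush(3, "disc"))
  20 + 200 * thick
}

#' Ground-truth CCFD% per grid box
#'
#' Computes, on the noise-free reference-frame truth masks, the
#' percentage of deficit pixels among non-excluded pixels in each grid
#' box — the oracle against which measured box CCFD% is compared.
#'
#' @param truth A `synthetic_truth` from [generate_case()].
#' @param grid A `grid_spec` from [tile_grid()] on the reference frame.
#' @param visit_index Visit whose truth deficit mask to use (0..3).
#' @return Named numeric vector: `box_id` -> percent (`NA` when a box has
#'   no non-excluded pixels).
#' @export
truth_box_ccfd <- function(truth, grid, visit_index = 0L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(grid, "grid_spec"),
            visit_index %in% 0:3)
  deficit <- truth$deficit_mask[[visit_index + 1L]]
  excl <- truth$hypotd_mask
  b <- grid$box_px
  boxes <- grid$boxes
  if (any(boxes$row0 + b - 1L > nrow(deficit)) ||
      any(boxes$col0 + b - 1L > ncol(deficit)))
    stop("box outside truth raster")
  out <- vapply(seq_len(nrow(boxes)), function(i) {
    r <- boxes$row0[i]:(boxes$row0[i] + b - 1L)
    cl <- boxes$col0[i]:(boxes$col0[i] + b - 1L)
    d <- deficit[r, cl]; e <- excl[r, cl]
    denom <- sum(!e)
    if (denom == 0) return(NA_real_)
    100 * sum(d & !e) / denom
  }, numeric(1))
  names(out) <- boxes$box_id
  out
}

#' Simulate a box-observation table directly
#'
#' Draws CCFD% observations from the nested random-intercept model
#' (patients, eyes within patients, boxes within eyes, residual) with a
#' per-visit fixed effect — the data-generating process matching the
#' group-level analysis, used to validate the mixed-model stage without
#' rendering images.
#'
#' @param n_patients Number of patients (one eye each by default).
#' @param eyes_per_patient Eyes per patient.
#' @param boxes_per_eye Boxes per eye.
#' @param visit_effect Length-4 numeric: mean CCFD% shift per visit.
#' @param baseline_mean Grand mean CCFD%.
#' @param sd_patient,sd_eye,sd_box,sd_resid Standard deviations of the
#'   random intercepts and residual.
#' @param category Category label written on every row.
#' @param seed Integer seed.
#' @return A tibble in the box-table schema.
#' @export
simulate_box_table <- function(n_patients = 24L, eyes_per_patient = 1L,
                               boxes_per_eye = 27L,
                               visit_effect = c(0, 0, 3, 3),
                               baseline_mean = 8,
                               sd_patient = 1.5, sd_eye = 0.5,
                               sd_box = 2, sd_resid = 1.5,
                               category = "target", seed = 1L) {
  stopifnot(length(visit_effect) == 4)
  with_seed(seed, {
    rows <- expand.grid(visit_index = 0:3,
                        box = seq_len(boxes_per_eye),
                        eye = seq_len(eyes_per_patient),
                        patient = seq_len(n_patients))
    u_pat <- rnorm(n_patients, 0, sd_patient)
    u_eye <- rnorm(n_patients * eyes_per_patient, 0, sd_eye)
    n_box <- n_patients * eyes_per_patient * boxes_per_eye
    u_box <- rnorm(n_box, 0, sd_box)
    eye_ix <- (rows$patient - 1L) * eyes_per_patient + rows$eye
    box_ix <- (eye_ix - 1L) * boxes_per_eye + rows$box
    y <- baseline_mean + visit_effect[rows$visit_index + 1L] +
      u_pat[rows$patient] + u_eye[eye_ix] + u_box[box_ix] +
      rnorm(nrow(rows), 0, sd_resid)
    tibble::tibble(
      patient_id = sprintf("pt%02d", rows$patient),
      eye_id = sprintf("pt%02d_eye%d", rows$patient, rows$eye),
      box_id = rows$box,
      visit_index = rows$visit_index,
      category = category,
      ccfd_pct = pmin(pmax(y, 0), 100),
      valid_frac = 1,
      included = TRUE)
  })
}
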