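#' Smooth the sub-RPE reference slab
#'
#' High-frequency noise in the sub-RPE structure slab destabilizes the
#' gamma optimization, so the reference is low-pass filtered with a
#' truncated Gaussian kernel (default 13 x 13 px, sigma 15) before use.
#' Borders are handled by reflection, which preserves total mass, and the
#' output is floored at a small epsilon so later normalization never
#' divides by zero.
#'
#' @param subrpe_structure An [enface_image()] (`subrpe_structure` slab).
#' @param config A [ccfd_config()].
#' @return The filtered `enface_image`.
#' @export
smooth_reference <- function(subrpe_structure, config = ccfd_config()) {
  stopifnot(inherits(subrpe_structure, "enface_image"))
  px <- subrpe_structure$pixels
  if (length(px) == 0) stop("raster is empty")
  k <- gaussian_kernel(config$smooth_kernel_px, config$smooth_sigma)
  sm <- convolve_reflect(px, k)
  eps <- 1e-3 * max(max(sm), 1)
  sm <- pmax(sm, eps)
  enface_image(sm, spacing_um = subrpe_structure$spacing_um,
               slab_name = subrpe_structure$slab_name)
}

# Normalized truncated Gaussian kernel, side k (odd), sigma in px.
gaussian_kernel <- function(k, sigma) {
  stopifnot(k %% 2 == 1)
  r <- (k - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  kk <- outer(g, g)
  kk / sum(kk)
}

# 2-D convolution with reflective (mirror) border handling.
convolve_reflect <- function(px, kernel) {
  r <- (nrow(kernel) - 1) / 2
  n <- nrow(px); m <- ncol(px)
  if (r == 0) return(px * kernel[1, 1])
  ridx <- c(r:1, 1:n, n:(n - r + 1))
  cidx <- c(r:1, 1:m, m:(m - r + 1))
  padded <- px[ridx, cidx, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(r + 1):(r + n), (r + 1):(r + m), drop = FALSE]
}

#' Apply gamma compensation to CC slabs
#'
#' Shadowed CC signal under drusen is corrected multiplicatively: the
#' smoothed sub-RPE reference is normalized by its 99th percentile and
#' clipped to `[eps, 1]`, and each unmasked pixel is scaled by
#' `N(x)^(-gamma)`. Pixels under the hyperTD compensation mask keep a
#' factor of 1 so bright lesions are never inverted into artifactual
#' deficits. Outputs are clipped at the input slab's dynamic-range
#' ceiling (its maximum) to bound amplification in deep shadows.
#'
#' @param flow,cc_structure CC flow and structure [enface_image()]s.
#' @param reference The smoothed sub-RPE reference ([smooth_reference()]).
#' @param comp_mask HyperTD compensation [mask_image()]; masked pixels are
#'   left numerically unchanged.
#' @param gamma Non-negative compensation exponent.
#' @return A list with `flow` and `structure` compensated `enface_image`s.
#' @export
compensate <- function(flow, cc_structure, reference, comp_mask, gamma) {
  stopifnot(inherits(flow, "enface_image"),
            inherits(cc_structure, "enface_image"),
            inherits(reference, "enface_image"),
            inherits(comp_mask, "mask_image"))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    stop("gamma must be a non-negative scalar")
  dims <- list(dim(flow$pixels), dim(cc_structure$pixels),
               dim(reference$pixels), dim(comp_mask$pixels))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("shape mismatch between slabs, reference and mask")
  f <- comp_factor(reference$pixels, comp_mask$pixels, gamma)
  comp_one <- function(img) {
    ceiling_val <- max(img$pixels)
    out <- pmin(img$pixels * f, ceiling_val)
    enface_image(out, spacing_um = img$spacing_um, slab_name = img$slab_name)
  }
  list(flow = comp_one(flow), structure = comp_one(cc_structure))
}

# Per-pixel compensation factor N^(-gamma), 1 under the mask. The 99th-
# percentile normalization ceiling is estimated outside the hyperTD mask:
# it must represent unattenuated normal tissue, and hyperTD brightness is
# pathological transmission, exactly what the mask marks.
comp_factor <- function(ref_px, mask_px, gamma) {
  p99 <- ref_p99(ref_px, mask_px)
  N <- pmin(pmax(ref_px / p99, 1e-3), 1)
  f <- N^(-gamma)
  f[mask_px] <- 1
  f
}

ref_p99 <- function(ref_px, mask_px = NULL) {
  vals <- if (!is.null(mask_px) && any(mask_px) && !all(mask_px))
    ref_px[!mask_px] else ref_px
  p99 <- as.numeric(quantile(vals, 0.99, names = FALSE))
  if (p99 <= 0) 1 else p99
}

#' Optimize the compensation gamma for one scan
#'
#' Evaluates every candidate gamma on the grid and selects the one whose
#' compensated CC structure slab is most homogeneous, i.e. has the lowest
#' standard deviation over eligible pixels: outside the hyperTD
#' compensation mask, the exclusion mask, and (when supplied) the
#' low-signal mask — noise-floor pixels respond to the compensation
#' factor without carrying signal and would otherwise dominate the
#' objective. The objective uses the unclipped compensated values (the
#' dynamic-range clip is an export concern; inside the objective it
#' collapses sd to zero at large gamma). Ties break toward the smaller
#' gamma, so a flat reference yields no compensation.
#'
#' @param cc_structure CC structure [enface_image()].
#' @param reference Smoothed sub-RPE reference [enface_image()].
#' @param comp_mask HyperTD compensation [mask_image()].
#' @param exclusion_mask Exclusion [mask_image()] (hypoTDs etc.).
#' @param config A [ccfd_config()] supplying `gamma_grid`.
#' @param low_sig Optional low-signal [mask_image()] from
#'   [low_signal_mask()]; its pixels are removed from the objective.
#' @return A list of class `compensation_result` with `gamma_star`,
#'   `objective_curve` (named numeric: sd per gamma), and `eligible_n`.
#' @export
optimize_gamma <- function(cc_structure, reference, comp_mask,
                           exclusion_mask, config = ccfd_config(),
                           low_sig = NULL) {
  stopifnot(inherits(cc_structure, "enface_image"),
            inherits(reference, "enface_image"))
  eligible <- !comp_mask$pixels & !exclusion_mask$pixels
  if (!is.null(low_sig)) eligible <- eligible & !low_sig$pixels
  n_el <- sum(eligible)
  if (n_el < 100)
    stop("unquantifiable scan: only ", n_el,
         " eligible pixels for gamma optimization (need >= 100)")
  p99 <- ref_p99(reference$pixels, comp_mask$pixels)
  N_el <- pmin(pmax(reference$pixels[eligible] / p99, 1e-3), 1)
  s_el <- cc_structure$pixels[eligible]
  # the objective is a smooth functional of the intensity distribution;
  # a deterministic stride subsample (<= 50k px) estimates it to ~0.3%
  if (length(s_el) > 50000L) {
    idx <- seq.int(1L, length(s_el),
                   by = ceiling(length(s_el) / 50000L))
    N_el <- N_el[idx]; s_el <- s_el[idx]
  }
  logN <- log(N_el)
  n_obj <- length(s_el)
  grid <- config$gamma_grid
  objective <- vapply(grid, function(g) {
    y <- s_el * exp(-g * logN)
    sqrt((sum(y * y) - sum(y)^2 / n_obj) / (n_obj - 1))
  }, numeric(1))
  names(objective) <- formatC(grid, format = "f", digits = 1)
  best <- which(objective <= min(objective) + 1e-12)[1]  # ties -> smaller gamma
  structure(list(gamma_star = grid[best],
                 objective_curve = objective,
                 eligible_n = n_el),
            class = "compensation_result")
}
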