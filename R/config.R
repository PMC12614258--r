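#' Analysis configuration
#'
#' Collects every tunable parameter of the CCFD quantification pipeline.
#' Defaults follow the published grid-box strategy for 6 x 6-mm scans
#' sampled at 500 A-scans per B-scan (12 um/px).
#'
#' @param box_px Grid-box side in pixels (74 px is about 0.9 mm at 12 um/px).
#' @param max_invalid_frac A box is excluded when more than this fraction of
#'   its area is unavailable (masked or low signal) at any visit.
#' @param low_signal_db Margin in dB over the median background signal below
#'   which pixels are considered low-signal.
#' @param mdc_pct Minimal detectable change in CCFD percentage points; box
#'   changes with absolute value strictly above this are flagged as real.
#' @param min_deficit_diam_um Flow-deficit components with equivalent
#'   circular diameter below this (physiological intercapillary distance)
#'   are removed.
#' @param gamma_grid Candidate gamma values for compensation optimization,
#'   sorted increasing.
#' @param smooth_kernel_px Side of the truncated Gaussian kernel applied to
#'   the sub-RPE reference slab before gamma optimization.
#' @param smooth_sigma Sigma (in pixels) of that Gaussian kernel.
#' @param search_radius_px Registration search window half-width in pixels.
#' @param spacing_um Physical pixel spacing in micrometers.
#' @param zncc_min Minimum acceptable registration peak correlation; below
#'   this the case is treated as unregisterable.
#' @param rng_seed Integer seed used by simulation helpers when set.
#'
#' @return A list of class `ccfd_config`.
#' @export
ccfd_config <- function(box_px = 74L,
                        max_invalid_frac = 0.25,
                        low_signal_db = 5,
                        mdc_pct = 5,
                        min_deficit_diam_um = 24,
                        gamma_grid = seq(0, 5, by = 0.1),
                        smooth_kernel_px = 13L,
                        smooth_sigma = 15,
                        search_radius_px = 32L,
                        spacing_um = 12,
                        zncc_min = 0.2,
                        rng_seed = NULL) {
  stopifnot(box_px > 0, max_invalid_frac > 0, low_signal_db > 0,
            mdc_pct > 0, min_deficit_diam_um > 0,
            smooth_kernel_px > 0, smooth_sigma > 0,
            search_radius_px > 0, spacing_um > 0, zncc_min > 0)
  if (length(gamma_grid) == 0 || is.unsorted(gamma_grid) || any(gamma_grid < 0))
    stop("gamma_grid must be nonempty, sorted and non-negative")
  structure(list(
    box_px = as.integer(box_px),
    max_invalid_frac = max_invalid_frac,
    low_signal_db = low_signal_db,
    mdc_pct = mdc_pct,
    min_deficit_diam_um = min_deficit_diam_um,
    gamma_grid = gamma_grid,
    smooth_kernel_px = as.integer(smooth_kernel_px),
    smooth_sigma = smooth_sigma,
    search_radius_px = as.integer(search_radius_px),
    spacing_um = spacing_um,
    zncc_min = zncc_min,
    rng_seed = rng_seed
  ), class = "ccfd_config")
}

#' Read / write a configuration as YAML
#'
#' The YAML file mirrors the field names of [ccfd_config()].
#'
#' @param path File path.
#' @return For `read_config`, a `ccfd_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ccfd_config, vals)
}

#' @rdname read_config
#' @param config A `ccfd_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ccfd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Scan geometry facts
#'
#' Derives the physical geometry of the scan and grid from first
#' principles: pixel spacing from the scan width and A-scan count, the
#' grid-box side and area, and the CC slab thickness from its depth
#' boundaries beneath Bruch's membrane.
#'
#' @param scan_mm Scan width in millimeters (fovea-centered pattern).
#' @param n_ascans A-scans per B-scan (pixels across the scan).
#' @param box_px Grid-box side in pixels.
#' @param cc_slab_um Depth boundaries of the CC slab beneath Bruch's
#'   membrane, in micrometers, as `c(inner, outer)`.
#'
#' @return A list with `spacing_um`, `box_mm` (side, rounded to the 0.1 mm
#'   the instrument resolves), `box_area_mm2`, and `cc_slab_thickness_um`.
#' @export
scan_geometry <- function(scan_mm = 6, n_ascans = 500L, box_px = 74L,
                          cc_slab_um = c(4, 20)) {
  spacing_um <- scan_mm * 1000 / n_ascans
  box_mm <- round(box_px * spacing_um / 1000, 1)
  list(spacing_um = spacing_um,
       box_mm = box_mm,
       box_area_mm2 = box_mm^2,
       cc_slab_thickness_um = diff(cc_slab_um))
}
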