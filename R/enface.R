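#' En face image
#'
#' A 2-D non-negative intensity raster with physical pixel spacing.
#' Coordinates are 1-based `(row, col)` in R convention; boxes and shifts
#' use half-open pixel ranges in this frame.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param spacing_um Pixel spacing in micrometers (> 0).
#' @param slab_name One of `"cc_flow"`, `"cc_structure"`,
#'   `"subrpe_structure"`, `"vasculature"`.
#'
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, spacing_um = 12,
                         slab_name = c("cc_flow", "cc_structure",
                                       "subrpe_structure", "vasculature")) {
  slab_name <- match.arg(slab_name)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("spacing_um must be a positive scalar")
  structure(list(pixels = pixels, spacing_um = spacing_um,
                 slab_name = slab_name),
            class = "enface_image")
}

#' Mask image
#'
#' A boolean raster companion to an [enface_image()].
#'
#' @param pixels Logical matrix.
#' @param kind One of `"exclusion"`, `"hypertd"`, `"vessel"`,
#'   `"low_signal"`, `"integrated"`.
#'
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(pixels, kind = c("exclusion", "hypertd", "vessel",
                                        "low_signal", "integrated")) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels) || !is.logical(pixels) || anyNA(pixels))
    stop("pixels must be a logical matrix without NA")
  structure(list(pixels = pixels, kind = kind), class = "mask_image")
}

#' Binary CCFD map
#'
#' Tri-state raster classifying each pixel of the compensated CC flow slab
#' as flow (0), deficit (1) or invalid (2). Invalid pixels cover the
#' integrated exclusion mask, retinal-vessel projections, and borders
#' introduced by registration.
#'
#' @param state Integer matrix with values in `{0, 1, 2}`.
#' @param spacing_um Pixel spacing in micrometers.
#' @return An object of class `ccfd_map`.
#' @export
ccfd_map <- function(state, spacing_um = 12) {
  if (!is.matrix(state) || !is.integer(state))
    stop("state must be an integer matrix")
  if (anyNA(state) || !all(state %in% c(CCFD_FLOW, CCFD_DEFICIT, CCFD_INVALID)))
    stop("state values must be 0 (flow), 1 (deficit) or 2 (invalid)")
  structure(list(state = state, spacing_um = spacing_um), class = "ccfd_map")
}

#' Transform
#'
#' Integer pixel translation `(dy, dx)` that maps a moving visit onto the
#' reference visit: applying it moves content down by `dy` rows and right
#' by `dx` columns.
#'
#' @param dy,dx Integer displacements.
#' @param zncc_peak Peak correlation at the estimated shift (optional).
#' @return An object of class `ccfd_transform`.
#' @export
ccfd_transform <- function(dy, dx, zncc_peak = NA_real_) {
  stopifnot(dy == round(dy), dx == round(dx))
  structure(list(dy = as.integer(dy), dx = as.integer(dx),
                 zncc_peak = zncc_peak),
            class = "ccfd_transform")
}

#' Visit record
#'
#' One visit's en face slabs, masks and identifiers. All rasters must
#' share one shape. Visit indices run 0..3: 0 is one year pre-onset, 1 is
#' the hyperTD onset (T = 0), 2 and 3 are one and two years post-onset.
#'
#' @param visit_index Integer in 0..3.
#' @param cc_flow,cc_structure,subrpe_structure,vasculature `enface_image`s.
#' @param exclusion_mask,hypertd_mask `mask_image`s.
#' @param vessel_mask Optional `mask_image` of retinal-vessel projections.
#' @param eye_id,patient_id Identifiers.
#' @return An object of class `visit_record`.
#' @export
visit_record <- function(visit_index, cc_flow, cc_structure,
                         subrpe_structure, vasculature,
                         exclusion_mask, hypertd_mask, vessel_mask = NULL,
                         eye_id = "eye1", patient_id = "pt1") {
  stopifnot(visit_index %in% 0:3)
  slabs <- list(cc_flow = cc_flow, cc_structure = cc_structure,
                subrpe_structure = subrpe_structure,
                vasculature = vasculature)
  for (nm in names(slabs)) {
    if (!inherits(slabs[[nm]], "enface_image"))
      stop("slab '", nm, "' is not an enface_image")
  }
  masks <- list(exclusion_mask = exclusion_mask, hypertd_mask = hypertd_mask)
  if (!is.null(vessel_mask)) masks$vessel_mask <- vessel_mask
  for (nm in names(masks)) {
    if (!inherits(masks[[nm]], "mask_image"))
      stop("mask '", nm, "' is not a mask_image")
  }
  ref_dim <- dim(cc_flow$pixels)
  all_dims <- c(lapply(slabs, function(s) dim(s$pixels)),
                lapply(masks, function(m) dim(m$pixels)))
  for (nm in names(all_dims)) {
    if (!identical(all_dims[[nm]], ref_dim))
      stop("shape mismatch: '", nm, "' is ",
           paste(all_dims[[nm]], collapse = "x"), " but cc_flow is ",
           paste(ref_dim, collapse = "x"))
  }
  structure(list(visit_index = as.integer(visit_index),
                 cc_flow = cc_flow, cc_structure = cc_structure,
                 subrpe_structure = subrpe_structure,
                 vasculature = vasculature,
                 exclusion_mask = exclusion_mask,
                 hypertd_mask = hypertd_mask,
                 vessel_mask = vessel_mask,
                 eye_id = eye_id, patient_id = patient_id),
            class = "visit_record")
}

#' @method print enface_image
#' @export
print.enface_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<enface_image %s %dx%d @ %g um/px, range [%g, %g]>\n",
              x$slab_name, d[1], d[2], x$spacing_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @method print ccfd_map
#' @export
print.ccfd_map <- function(x, ...) {
  tab <- tabulate(x$state + 1L, nbins = 3L)
  cat(sprintf("<ccfd_map %dx%d: %d flow, %d deficit, %d invalid>\n",
              nrow(x$state), ncol(x$state), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @method print ccfd_transform
#' @export
print.ccfd_transform <- function(x, ...) {
  cat(sprintf("<transform dy=%d dx=%d zncc=%.3f>\n", x$dy, x$dx, x$zncc_peak))
  invisible(x)
}
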