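#' Fuzzy C-means global threshold
#'
#' Two-cluster fuzzy C-means with fuzzifier m = 2, run on a 256-bin
#' histogram of the valid pixels of the compensated CC flow slab. The
#' histogram formulation makes the threshold a deterministic function of
#' the intensity distribution. Centers initialize at the 25th and 75th
#' percentiles and iterate until the largest center movement falls below
#' 1e-6 (or 500 iterations). The reported threshold is the midpoint of
#' the two converged centers — the equal-membership point for m = 2.
#'
#' @param image Compensated CC flow [enface_image()].
#' @param valid_mask Optional [mask_image()]; `TRUE` pixels are *excluded*
#'   from the histogram (exclusion semantics). `NULL` uses all pixels.
#' @param config A [ccfd_config()] (reserved; bins and tolerances are
#'   fixed conventions).
#' @return A list of class `fcm_result` with `centers` (`c(low, high)`),
#'   `threshold`, `n_iter`, `objective`.
#' @export
fcm_threshold <- function(image, valid_mask = NULL, config = ccfd_config()) {
  stopifnot(inherits(image, "enface_image"))
  px <- image$pixels
  if (!is.null(valid_mask)) {
    stopifnot(inherits(valid_mask, "mask_image"))
    if (!identical(dim(valid_mask$pixels), dim(px)))
      stop("valid_mask shape mismatch")
    px <- px[!valid_mask$pixels]
  }
  if (length(unique(as.numeric(px))) < 2)
    stop("degenerate histogram: all valid pixels are equal")
  h <- intensity_histogram(px, bins = 256L)
  fit <- fcm_histogram(h$mids, h$weights, m = 2,
                       tol = 1e-6, max_iter = 500L)
  centers <- sort(fit$centers)
  structure(list(centers = centers,
                 threshold = mean(centers),
                 n_iter = fit$n_iter,
                 objective = fit$objective),
            class = "fcm_result")
}

# 256-bin histogram over the value range; returns bin midpoints + weights.
intensity_histogram <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  w <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  keep <- w > 0
  list(mids = mids[keep], weights = w[keep])
}

# Weighted 2-cluster FCM (m = 2) on histogram bins.
fcm_histogram <- function(x, w, m = 2, tol = 1e-6, max_iter = 500L) {
  centers <- as.numeric(quantile(rep.int(x, w), c(0.25, 0.75), names = FALSE))
  if (diff(centers) < .Machine$double.eps)
    centers <- range(x)
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-300)
    # memberships for m = 2: u_ik proportional to 1/d2
    inv <- 1 / d2
    u <- inv / rowSums(inv)
    u2w <- u^2 * w
    new_centers <- colSums(u2w * x) / colSums(u2w)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < tol) break
  }
  d2 <- outer(x, centers, function(a, b) (a - b)^2)
  inv <- 1 / pmax(d2, 1e-300)
  u <- inv / rowSums(inv)
  objective <- sum((u^2 * w) * d2)
  list(centers = centers, n_iter = it, objective = objective)
}

#' Binarize the compensated CC flow slab
#'
#' Classifies each pixel: invalid if covered by the integrated exclusion
#' mask or the retinal-vessel mask, otherwise deficit when its intensity
#' is strictly below the FCM threshold, otherwise flow.
#'
#' @param flow_comp Compensated CC flow [enface_image()].
#' @param fcm An `fcm_result` from [fcm_threshold()].
#' @param integrated_mask Exclusion [mask_image()].
#' @param vessel_mask Optional retinal-vessel [mask_image()].
#' @return A [ccfd_map()].
#' @export
binarize <- function(flow_comp, fcm, integrated_mask, vessel_mask = NULL) {
  stopifnot(inherits(flow_comp, "enface_image"), inherits(fcm, "fcm_result"),
            inherits(integrated_mask, "mask_image"))
  px <- flow_comp$pixels
  if (!identical(dim(integrated_mask$pixels), dim(px)))
    stop("integrated_mask shape mismatch")
  invalid <- integrated_mask$pixels
  if (!is.null(vessel_mask)) {
    stopifnot(inherits(vessel_mask, "mask_image"))
    if (!identical(dim(vessel_mask$pixels), dim(px)))
      stop("vessel_mask shape mismatch")
    invalid <- invalid | vessel_mask$pixels
  }
  state <- matrix(CCFD_FLOW, nrow(px), ncol(px))
  state[px < fcm$threshold] <- CCFD_DEFICIT
  state[invalid] <- CCFD_INVALID
  storage.mode(state) <- "integer"
  ccfd_map(state, spacing_um = flow_comp$spacing_um)
}

#' Remove sub-capillary flow deficits
#'
#' Drops 8-connected deficit components whose equivalent circular
#' diameter, `2 * spacing * sqrt(area_px / pi)`, is below the
#' physiological intercapillary distance (default 24 um); their pixels
#' are reassigned to flow. Invalid pixels are never touched.
#'
#' @param map A [ccfd_map()].
#' @param config A [ccfd_config()] supplying `min_deficit_diam_um`.
#' @return The filtered `ccfd_map`.
#' @export
remove_small_deficits <- function(map, config = ccfd_config()) {
  stopifnot(inherits(map, "ccfd_map"))
  deficit <- map$state == CCFD_DEFICIT
  if (!any(deficit)) return(map)
  lab <- label_components8(deficit)
  areas <- tabulate(lab[lab > 0L])
  diam_um <- 2 * map$spacing_um * sqrt(areas / pi)
  drop_ids <- which(diam_um < config$min_deficit_diam_um)
  if (length(drop_ids)) {
    state <- map$state
    state[lab %in% drop_ids] <- CCFD_FLOW
    map <- ccfd_map(state, spacing_um = map$spacing_um)
  }
  map
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass over label pairs.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-n, -m]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -m]), as.vector(lab[-n, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}
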