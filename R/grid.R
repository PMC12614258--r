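#' Place the target box
#'
#' Centers a `box_px`-sided box on the centroid of the annotated target
#' hyperTD (reference frame), rounding the centroid to the nearest pixel
#' and clamping so the box lies fully inside the raster.
#'
#' @param target_annotation A nonempty [mask_image()] of the target
#'   hyperTD on the reference frame.
#' @param config A [ccfd_config()] supplying `box_px`.
#' @return Integer `c(row0, col0)` of the box's top-left pixel (1-based).
#' @export
make_target_box <- function(target_annotation, config = ccfd_config()) {
  stopifnot(inherits(target_annotation, "mask_image"))
  idx <- which(target_annotation$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("target annotation is empty")
  centroid <- round(colMeans(idx))
  b <- config$box_px
  top <- centroid - b %/% 2
  lim <- dim(target_annotation$pixels) - b + 1L
  if (any(lim < 1L)) stop("box does not fit inside the raster")
  as.integer(pmin(pmax(top, 1L), lim))
}

#' Tile the grid around the target box
#'
#' Lays a lattice of complete, non-overlapping `box_px` boxes anchored at
#' the target box's top-left (modulo `box_px` in both axes), extending
#' until a full row or column of boxes no longer fits. Boxes are
#' enumerated row-major.
#'
#' @param shape Raster dimensions `c(nrow, ncol)`.
#' @param target_box Target box top-left `c(row0, col0)` from
#'   [make_target_box()].
#' @param config A [ccfd_config()].
#' @return A list of class `grid_spec` with `boxes` (data frame of
#'   `box_id`, `row0`, `col0`), `box_px`, `target_box_id`, `shape`, and
#'   lattice dimensions `n_rows`, `n_cols`.
#' @export
tile_grid <- function(shape, target_box, config = ccfd_config()) {
  b <- config$box_px
  stopifnot(length(shape) == 2, all(target_box >= 1),
            all(target_box + b - 1L <= shape))
  off <- (as.integer(target_box) - 1L) %% b
  starts_r <- seq.int(off[1] + 1L, by = b,
                      length.out = (shape[1] - off[1]) %/% b)
  starts_c <- seq.int(off[2] + 1L, by = b,
                      length.out = (shape[2] - off[2]) %/% b)
  boxes <- expand.grid(col0 = starts_c, row0 = starts_r)[, c("row0", "col0")]
  boxes <- data.frame(box_id = seq_len(nrow(boxes)), boxes)
  target_box_id <- boxes$box_id[boxes$row0 == target_box[1] &
                                boxes$col0 == target_box[2]]
  stopifnot(length(target_box_id) == 1)
  structure(list(boxes = boxes, box_px = b, target_box_id = target_box_id,
                 shape = as.integer(shape),
                 n_rows = length(starts_r), n_cols = length(starts_c)),
            class = "grid_spec")
}

#' Categorize grid boxes
#'
#' The designated target box is `target`. Any other box overlapping any
#' hyperTD pixel at any visit — including spillover of the target lesion
#' beyond its box — is `nontarget_hypertd`. Remaining boxes are
#' `adjacent_background` when they 8-neighbour (share an edge or corner
#' on the box lattice with) any hyperTD-overlapping box, else
#' `nonadjacent_background`. Categories are frozen across all visits.
#'
#' @param grid A `grid_spec` from [tile_grid()].
#' @param hypertd_masks_by_visit List of registered hyperTD
#'   [mask_image()]s, one per visit.
#' @return Named character vector: `box_id` -> category.
#' @export
classify_boxes <- function(grid, hypertd_masks_by_visit) {
  stopifnot(inherits(grid, "grid_spec"), length(hypertd_masks_by_visit) >= 1)
  any_hyper <- Reduce(`|`, lapply(hypertd_masks_by_visit, `[[`, "pixels"))
  b <- grid$box_px
  boxes <- grid$boxes
  overlaps <- vapply(seq_len(nrow(boxes)), function(i) {
    r0 <- boxes$row0[i]; c0 <- boxes$col0[i]
    any(any_hyper[r0:(r0 + b - 1L), c0:(c0 + b - 1L)])
  }, logical(1))
  lat_r <- (boxes$row0 - min(boxes$row0)) %/% b + 1L
  lat_c <- (boxes$col0 - min(boxes$col0)) %/% b + 1L
  hyper_cells <- cbind(lat_r[overlaps], lat_c[overlaps])
  adjacent <- vapply(seq_len(nrow(boxes)), function(i) {
    if (nrow(hyper_cells) == 0) return(FALSE)
    any(abs(hyper_cells[, 1] - lat_r[i]) <= 1 &
        abs(hyper_cells[, 2] - lat_c[i]) <= 1)
  }, logical(1))
  category <- ifelse(overlaps, "nontarget_hypertd",
                     ifelse(adjacent, "adjacent_background",
                            "nonadjacent_background"))
  category[grid$target_box_id] <- "target"
  names(category) <- boxes$box_id
  category
}

#' Low-signal mask
#'
#' Marks pixels of the CC structure slab whose intensity falls below
#' 5 dB (power convention, `10^(5/10)`) above the median background
#' level, estimated as the median of the darkest 5% of pixels. The
#' pipeline applies this to the *uncompensated* structure slab: signal
#' quality is a property of the acquired signal — compensation amplifies
#' noise-floor regions toward tissue level without adding information,
#' so they must be caught before amplification.
#'
#' @param cc_structure CC structure [enface_image()] (raw).
#' @param config A [ccfd_config()] supplying `low_signal_db`.
#' @return A `mask_image` of kind `"low_signal"`.
#' @export
low_signal_mask <- function(cc_structure, config = ccfd_config()) {
  stopifnot(inherits(cc_structure, "enface_image"))
  px <- cc_structure$pixels
  dark <- quantile(px, 0.05, names = FALSE)
  background <- median(px[px <= dark])
  thresh <- background * 10^(config$low_signal_db / 10)
  mask_image(px < thresh, kind = "low_signal")
}

#' Per-box CCFD percentage
#'
#' Within one box, `unavailable` pixels are those invalid on the CCFD map
#' or flagged low-signal; `valid_frac` is the available fraction, and
#' `ccfd_pct` is `100 * deficit / (deficit + flow)` over available
#' pixels (missing when no pixel is available). The inclusion rule —
#' strictly more than 25% unavailable excludes the box — is applied
#' study-wide by [box_table()].
#'
#' @param map Registered, integrated-masked [ccfd_map()].
#' @param box `c(row0, col0)` top-left of the box.
#' @param low_sig Registered low-signal [mask_image()] (or `NULL`).
#' @param config A [ccfd_config()].
#' @return List with `ccfd_pct` (may be `NA`), `valid_frac`,
#'   `included_visit` (this visit's 25% check).
#' @export
box_ccfd <- function(map, box, low_sig = NULL, config = ccfd_config()) {
  stopifnot(inherits(map, "ccfd_map"))
  b <- config$box_px
  r <- box[1]:(box[1] + b - 1L); cl <- box[2]:(box[2] + b - 1L)
  if (box[1] < 1 || box[2] < 1 || max(r) > nrow(map$state) ||
      max(cl) > ncol(map$state))
    stop("box outside raster")
  st <- map$state[r, cl]
  unavailable <- st == CCFD_INVALID
  if (!is.null(low_sig)) unavailable <- unavailable | low_sig$pixels[r, cl]
  valid_frac <- 1 - sum(unavailable) / length(st)
  avail <- !unavailable
  n_def <- sum(st[avail] == CCFD_DEFICIT)
  n_flow <- sum(st[avail] == CCFD_FLOW)
  ccfd_pct <- if (n_def + n_flow > 0) 100 * n_def / (n_def + n_flow)
              else NA_real_
  list(ccfd_pct = ccfd_pct, valid_frac = valid_frac,
       included_visit = (1 - valid_frac) <= config$max_invalid_frac)
}

#' Assemble the long-format box table for one eye
#'
#' Computes every box's CCFD% at every visit, applies the study-wide
#' inclusion rule (a box failing the 25% availability check at any visit
#' is excluded at all visits), and attaches categories.
#'
#' @param maps_by_visit List of registered, integrated-masked
#'   [ccfd_map()]s (one per visit, in visit order starting at 0).
#' @param grid A `grid_spec`.
#' @param categories Named vector from [classify_boxes()].
#' @param low_sig_by_visit Optional list of registered low-signal masks.
#' @param eye_id,patient_id Identifiers.
#' @param config A [ccfd_config()].
#' @return A tibble with columns `patient_id`, `eye_id`, `box_id`,
#'   `visit_index`, `category`, `ccfd_pct`, `valid_frac`, `included`.
#' @export
box_table <- function(maps_by_visit, grid, categories,
                      low_sig_by_visit = NULL,
                      eye_id = "eye1", patient_id = "pt1",
                      config = ccfd_config()) {
  n_visits <- length(maps_by_visit)
  boxes <- grid$boxes
  rows <- vector("list", nrow(boxes) * n_visits)
  k <- 0L
  per_box_ok <- rep(TRUE, nrow(boxes))
  obs <- array(list(), c(nrow(boxes), n_visits))
  for (i in seq_len(nrow(boxes))) {
    for (v in seq_len(n_visits)) {
      o <- box_ccfd(maps_by_visit[[v]],
                    c(boxes$row0[i], boxes$col0[i]),
                    low_sig = if (!is.null(low_sig_by_visit))
                      low_sig_by_visit[[v]] else NULL,
                    config = config)
      obs[[i, v]] <- o
      per_box_ok[i] <- per_box_ok[i] && o$included_visit
    }
  }
  for (i in seq_len(nrow(boxes))) {
    for (v in seq_len(n_visits)) {
      o <- obs[[i, v]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = patient_id, eye_id = eye_id,
        box_id = boxes$box_id[i], visit_index = v - 1L,
        category = unname(categories[as.character(boxes$box_id[i])]),
        ccfd_pct = if (per_box_ok[i]) o$ccfd_pct else NA_real_,
        valid_frac = o$valid_frac,
        included = per_box_ok[i],
        stringsAsFactors = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Export a QC overlay of the grid on a CCFD map
#'
#' Writes the binary CCFD palette (flow black, deficit white, invalid
#' gray) with box borders drawn in mid-gray and the target box in a
#' brighter border, for visual review of grid placement.
#'
#' @param map A registered [ccfd_map()].
#' @param grid A `grid_spec`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_grid_overlay <- function(map, grid, path) {
  stopifnot(inherits(map, "ccfd_map"), inherits(grid, "grid_spec"))
  lut <- c(0, 255, 128) / 255
  img <- matrix(lut[map$state + 1L], nrow(map$state))
  b <- grid$box_px
  for (i in seq_len(nrow(grid$boxes))) {
    r0 <- grid$boxes$row0[i]; c0 <- grid$boxes$col0[i]
    r1 <- r0 + b - 1L; c1 <- c0 + b - 1L
    lev <- if (grid$boxes$box_id[i] == grid$target_box_id) 1 else 0.7
    img[c(r0, r1), c0:c1] <- lev
    img[r0:r1, c(c0, c1)] <- lev
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Flag marked CCFD changes against the MDC
#'
#' Compares each visit's CCFD% to the pre-onset baseline (visit 0); a
#' change is marked when its absolute value strictly exceeds the minimal
#' detectable change (default 5 percentage points), the bound on
#' test-retest variability for a single grid box.
#'
#' @param series Numeric per-visit CCFD% for one box, in visit order
#'   (index 0 first).
#' @param config A [ccfd_config()] supplying `mdc_pct`.
#' @return A data frame with `visit_index`, `delta` (vs. visit 0) and
#'   `marked_change` (`NA` for the baseline visit).
#' @export
mdc_change <- function(series, config = ccfd_config()) {
  if (length(series) < 2) stop("need at least two visits")
  if (is.na(series[1])) stop("baseline (visit 0) CCFD% is missing")
  delta <- series - series[1]
  marked <- abs(delta) > config$mdc_pct
  marked[1] <- NA
  data.frame(visit_index = seq_along(series) - 1L,
             delta = delta, marked_change = marked)
}
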