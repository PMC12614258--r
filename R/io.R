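#' Read and write en face rasters
#'
#' Slabs travel as 16-bit grayscale TIFF (8- or 16-bit PNG is decoded
#' too, but PNG encoding is 8-bit); masks as 8-bit PNG. Integer pixel
#' values round-trip exactly on the matching depth.
#'
#' @param path File path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param spacing_um Pixel spacing recorded on the returned image.
#' @param slab_name Slab semantics for the returned [enface_image()].
#' @return `read_slab` returns an `enface_image`; `write_slab` returns
#'   `path` invisibly.
#' @export
read_slab <- function(path, spacing_um = 12, slab_name = "cc_flow") {
  px <- read_raster(path)
  enface_image(px, spacing_um = spacing_um, slab_name = slab_name)
}

#' @rdname read_slab
#' @param image An `enface_image` with intensities in `[0, 65535]`.
#' @export
write_slab <- function(image, path) {
  stopifnot(inherits(image, "enface_image"))
  px <- image$pixels
  if (max(px) > 65535)
    stop("slab intensities exceed the 16-bit export ceiling")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(px) > 255)
      stop("PNG slab export is 8-bit; use TIFF for 16-bit data")
    png::writePNG(px / 255, path)
  } else stop("unsupported raster extension: ", path)
  invisible(path)
}

#' @rdname read_slab
#' @param kind Mask semantics for the returned [mask_image()].
#' @export
read_mask <- function(path, kind = "exclusion") {
  px <- read_raster(path)
  mask_image(px > 0, kind = kind)
}

#' @rdname read_slab
#' @param mask A `mask_image`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

# Decode a grayscale raster to an integer-valued numeric matrix on the
# native scale (0..255 or 0..65535).
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    info <- attr(png::readPNG(path, info = TRUE), "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    px <- png::readPNG(path) * (2^depth - 1)
  } else stop("unsupported raster extension: ", path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse gray-encoded RGB
  storage.mode(px) <- "double"
  round(px)
}

#' Export a binary CCFD map as an 8-bit PNG
#'
#' Uses the palette 0 = flow (black), 255 = deficit (white),
#' 128 = invalid (gray).
#'
#' @param map A [ccfd_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_ccfd_png <- function(map, path) {
  stopifnot(inherits(map, "ccfd_map"))
  lut <- c(0, 255, 128) / 255
  png::writePNG(matrix(lut[map$state + 1L], nrow(map$state)), path)
  invisible(path)
}

#' Load one visit from files
#'
#' Reads the four slabs and the masks of a visit, binarizes masks at
#' intensity > 0, and validates that every raster shares one shape.
#'
#' @param paths Named list or character vector with entries `cc_flow`,
#'   `cc_structure`, `subrpe_structure`, `vasculature`, `exclusion_mask`,
#'   `hypertd_mask`, and optionally `vessel_mask`.
#' @param visit_index Visit index 0..3.
#' @param eye_id,patient_id Identifiers.
#' @param config A [ccfd_config()] supplying `spacing_um`.
#' @return A [visit_record()].
#' @export
load_visit <- function(paths, visit_index, eye_id = "eye1",
                       patient_id = "pt1", config = ccfd_config()) {
  paths <- as.list(paths)
  need <- c("cc_flow", "cc_structure", "subrpe_structure", "vasculature",
            "exclusion_mask", "hypertd_mask")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("missing paths for: ", paste(missing, collapse = ", "))
  sp <- config$spacing_um
  slabs <- lapply(need[1:4], function(nm)
    read_slab(paths[[nm]], spacing_um = sp, slab_name = nm))
  names(slabs) <- need[1:4]
  excl <- read_mask(paths$exclusion_mask, kind = "exclusion")
  hyper <- read_mask(paths$hypertd_mask, kind = "hypertd")
  vessel <- if (!is.null(paths$vessel_mask))
    read_mask(paths$vessel_mask, kind = "vessel") else NULL
  visit_record(visit_index,
               cc_flow = slabs$cc_flow, cc_structure = slabs$cc_structure,
               subrpe_structure = slabs$subrpe_structure,
               vasculature = slabs$vasculature,
               exclusion_mask = excl, hypertd_mask = hyper,
               vessel_mask = vessel,
               eye_id = eye_id, patient_id = patient_id)
}

BOX_TABLE_COLS <- c("patient_id", "eye_id", "box_id", "visit_index",
                    "category", "ccfd_pct", "valid_frac", "included")

#' Write / read the long-format box table
#'
#' One row per (eye, box, visit) with a fixed column order so repeated
#' runs are byte-stable.
#'
#' @param observations A data frame of box observations (see
#'   [box_table()]).
#' @param path CSV path.
#' @return `write_box_table` returns `path` invisibly; `read_box_table`
#'   returns a tibble.
#' @export
write_box_table <- function(observations, path) {
  observations <- as.data.frame(observations)
  if (nrow(observations) == 0) stop("observations must be nonempty")
  missing <- setdiff(BOX_TABLE_COLS, names(observations))
  if (length(missing))
    stop("box table lacks columns: ", paste(missing, collapse = ", "))
  out <- observations[, BOX_TABLE_COLS]
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_box_table
#' @export
read_box_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character",
                                eye_id = "character",
                                box_id = "integer",
                                visit_index = "integer",
                                category = "character",
                                ccfd_pct = "numeric",
                                valid_frac = "numeric",
                                included = "logical"))
  tibble::as_tibble(df)
}

#' Write run metadata as JSON
#'
#' Records per-visit gamma, FCM threshold, registration transform and the
#' full configuration for reproducibility.
#'
#' @param meta A list of run metadata.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
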