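#' Quantify one visit
#'
#' Runs the single-visit stages: smooth the sub-RPE reference, optimize
#' gamma, compensate the CC slabs (hyperTD regions protected), threshold
#' the compensated flow slab by fuzzy C-means, binarize, remove
#' sub-capillary deficits, and derive the low-signal mask from the
#' compensated structure slab.
#'
#' @param visit A [visit_record()].
#' @param config A [ccfd_config()].
#' @return A list with `map` ([ccfd_map()]), `low_signal`
#'   ([mask_image()]), `gamma_star`, `fcm`, `compensated` slabs.
#' @export
quantify_visit <- function(visit, config = ccfd_config()) {
  stopifnot(inherits(visit, "visit_record"))
  low_sig <- low_signal_mask(visit$cc_structure, config)
  ref <- smooth_reference(visit$subrpe_structure, config)
  opt <- optimize_gamma(visit$cc_structure, ref, visit$hypertd_mask,
                        visit$exclusion_mask, config, low_sig = low_sig)
  comp <- compensate(visit$cc_flow, visit$cc_structure, ref,
                     visit$hypertd_mask, opt$gamma_star)
  fcm <- fcm_threshold(comp$flow, valid_mask = visit$exclusion_mask, config)
  map <- binarize(comp$flow, fcm, visit$exclusion_mask, visit$vessel_mask)
  map <- remove_small_deficits(map, config)
  list(map = map, low_signal = low_sig, gamma_star = opt$gamma_star,
       objective_curve = opt$objective_curve, fcm = fcm,
       compensated = comp)
}

#' Run the complete workflow on one 4-visit case
#'
#' Quantifies every visit, registers all visits to the final visit via
#' the retinal vasculature, propagates the transforms to the binary CCFD
#' maps and masks, merges the registered exclusion masks into the
#' integrated mask, places the target box on the reference-visit target
#' hyperTD, tiles the grid, categorizes boxes, and assembles the box
#' table with MDC flags for the target series.
#'
#' @param visits List of four [visit_record()]s in visit order (0..3).
#' @param config A [ccfd_config()].
#' @param target_annotation Optional [mask_image()] of the target
#'   hyperTD on the reference frame; defaults to the final visit's
#'   hyperTD mask.
#' @return A list of class `ccfd_case` with the box `table`, `grid`,
#'   `categories`, `target_mdc` flags, `transforms`, `integrated_mask`,
#'   registered `maps`, and per-visit `meta` (gamma, FCM threshold).
#' @export
run_case <- function(visits, config = ccfd_config(),
                     target_annotation = NULL) {
  if (length(visits) != 4)
    stop("expected 4 visit records, got ", length(visits))
  idx <- vapply(visits, `[[`, integer(1), "visit_index")
  if (!identical(idx, 0:3)) stop("visits must be ordered 0..3")

  stage <- function(what, v, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed at visit ", v, ": ",
           conditionMessage(e), call. = FALSE))
  }
  q <- lapply(0:3, function(v)
    stage("quantify", v, quantify_visit(visits[[v + 1]], config)))

  ref_visit <- visits[[4]]
  transforms <- lapply(0:3, function(v) {
    if (v == 3L) return(ccfd_transform(0L, 0L, zncc_peak = 1))
    stage("register", v,
          estimate_shift(visits[[v + 1]]$vasculature,
                         ref_visit$vasculature, config))
  })
  reg_maps <- lapply(0:3, function(v)
    apply_transform(q[[v + 1]]$map, transforms[[v + 1]]))
  reg_excl <- lapply(0:3, function(v)
    apply_transform(visits[[v + 1]]$exclusion_mask, transforms[[v + 1]]))
  reg_low <- lapply(0:3, function(v)
    apply_transform(q[[v + 1]]$low_signal, transforms[[v + 1]]))
  reg_hyper <- lapply(0:3, function(v)
    apply_transform(visits[[v + 1]]$hypertd_mask, transforms[[v + 1]]))

  integrated <- integrate_masks(reg_excl)
  for (v in 0:3) {
    st <- reg_maps[[v + 1]]$state
    st[integrated$pixels] <- CCFD_INVALID
    reg_maps[[v + 1]] <- ccfd_map(st, spacing_um = reg_maps[[v + 1]]$spacing_um)
  }

  if (is.null(target_annotation)) target_annotation <- ref_visit$hypertd_mask
  target_box <- stage("target-box", 3,
                      make_target_box(target_annotation, config))
  grid <- tile_grid(dim(ref_visit$cc_flow$pixels), target_box, config)
  categories <- classify_boxes(grid, reg_hyper)
  tbl <- box_table(reg_maps, grid, categories, low_sig_by_visit = reg_low,
                   eye_id = ref_visit$eye_id,
                   patient_id = ref_visit$patient_id, config = config)

  target_rows <- tbl[tbl$box_id == grid$target_box_id, ]
  target_mdc <- if (all(target_rows$included) &&
                    !is.na(target_rows$ccfd_pct[1]))
    mdc_change(target_rows$ccfd_pct[order(target_rows$visit_index)], config)
  else NULL

  meta <- lapply(0:3, function(v) list(
    visit_index = v,
    gamma_star = q[[v + 1]]$gamma_star,
    sd_at_gamma_star = unname(min(q[[v + 1]]$objective_curve)),
    sd_uncompensated = unname(q[[v + 1]]$objective_curve[[1]]),
    fcm_threshold = q[[v + 1]]$fcm$threshold,
    dy = transforms[[v + 1]]$dy, dx = transforms[[v + 1]]$dx,
    zncc_peak = transforms[[v + 1]]$zncc_peak))

  structure(list(table = tbl, grid = grid, categories = categories,
                 target_mdc = target_mdc, transforms = transforms,
                 integrated_mask = integrated, maps = reg_maps,
                 low_signal = reg_low, meta = meta, config = config),
            class = "ccfd_case")
}

#' Run a multi-eye study
#'
#' Runs [run_case()] on every case, pools the box tables, fits the four
#' category-level mixed models, and collects the per-target
#' change-versus-baseline series. Cases whose pipeline fails (e.g.
#' unregisterable vasculature) are excluded and listed with reasons.
#'
#' @param cases List of cases, each a list of four [visit_record()]s.
#' @param config A [ccfd_config()].
#' @param out_dir Optional output directory for the pooled table, the
#'   four contrast tables and the report.
#' @return A list of class `ccfd_study` with `box_table`, `report`
#'   (see [summarize_tables()]), `target_series`, `case_meta`,
#'   `exclusions`.
#' @export
run_study <- function(cases, config = ccfd_config(), out_dir = NULL) {
  if (length(cases) < 2) stop("need at least 2 cases")
  results <- vector("list", length(cases))
  exclusions <- list()
  for (i in seq_along(cases)) {
    results[[i]] <- tryCatch(run_case(cases[[i]], config),
                             error = function(e) e)
    if (inherits(results[[i]], "error")) {
      exclusions[[length(exclusions) + 1]] <- list(
        case = i, reason = conditionMessage(results[[i]]))
      results[i] <- list(NULL)
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all cases failed")
  pooled <- do.call(rbind, lapply(results[ok], `[[`, "table"))
  series <- do.call(rbind, lapply(which(ok), function(i) {
    mdc <- results[[i]]$target_mdc
    if (is.null(mdc)) return(NULL)
    eye <- results[[i]]$table$eye_id[1]
    cbind(data.frame(case = i, eye_id = eye), mdc)
  }))
  report <- summarize_tables(pooled, out_dir = out_dir)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_box_table(pooled, file.path(out_dir, "box_table.csv"))
    if (!is.null(series))
      write.csv(series, file.path(out_dir, "target_series.csv"),
                row.names = FALSE)
    write_run_metadata(list(
      config = unclass(config),
      cases = lapply(results[ok], `[[`, "meta"),
      exclusions = exclusions),
      file.path(out_dir, "run_metadata.json"))
  }
  structure(list(box_table = tibble::as_tibble(pooled), report = report,
                 target_series = series,
                 case_meta = lapply(results[ok], `[[`, "meta"),
                 exclusions = exclusions),
            class = "ccfd_study")
}
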