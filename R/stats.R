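#' Fit the nested random-intercept mixed model
#'
#' Models CCFD% against visit (categorical, four levels) with random
#' intercepts for patients, eyes clustered within patients, and grid
#' boxes clustered within eyes, fit by REML with Satterthwaite degrees
#' of freedom. A random intercept whose variance is estimated at zero
#' (singular fit) is removed and the model refit; intercepts whose
#' grouping factor has a single level are unidentifiable and dropped up
#' front. With no random effects left the model reduces to ordinary
#' least squares.
#'
#' @param table A box-observation table (see [box_table()] /
#'   [simulate_box_table()]).
#' @param group Optional category filter (e.g. `"target"`,
#'   `"background"` for both background classes, or any single
#'   category); `NULL` uses all rows.
#' @return A list of class `lmm_result` with the fitted `model`,
#'   `variance_components`, `fixed_effects` (per-visit estimated
#'   marginal means), `dropped_intercepts`, `n_boxes`, `group`.
#' @export
fit_lmm <- function(table, group = NULL) {
  df <- as.data.frame(table)
  if (!is.null(group)) {
    keep <- if (identical(group, "background"))
      df$category %in% c("adjacent_background", "nonadjacent_background")
    else df$category == group
    df <- df[keep, , drop = FALSE]
  }
  df <- df[df$included & !is.na(df$ccfd_pct), , drop = FALSE]
  if (nrow(df) == 0) stop("no included observations",
                          if (!is.null(group)) paste0(" for group '", group, "'"))
  if (length(unique(df$visit_index)) < 2)
    stop("need data from at least two visits")
  df$visit <- factor(df$visit_index, levels = sort(unique(df$visit_index)))
  df$patient <- factor(df$patient_id)
  df$eye <- factor(paste(df$patient_id, df$eye_id, sep = ":"))
  df$box <- factor(paste(df$eye, df$box_id, sep = ":"))

  terms <- c(patient = "(1 | patient)", eye = "(1 | eye)", box = "(1 | box)")
  lvls <- c(patient = nlevels(df$patient), eye = nlevels(df$eye),
            box = nlevels(df$box))
  dropped <- character(0)
  # unidentifiable nesting: a grouping factor must have > 1 level and be
  # coarser than the one nested inside it
  keep <- rep(TRUE, 3); names(keep) <- names(terms)
  if (lvls["patient"] < 2) keep["patient"] <- FALSE
  if (lvls["eye"] <= lvls["patient"] || lvls["eye"] < 2) keep["eye"] <- FALSE
  if (lvls["box"] <= lvls["eye"] || lvls["box"] < 2) keep["box"] <- FALSE
  dropped <- c(dropped, names(terms)[!keep])

  fit_with <- function(active) {
    if (!any(active)) return(stats::lm(ccfd_pct ~ visit, data = df))
    fml <- stats::as.formula(paste("ccfd_pct ~ visit +",
                                   paste(terms[active], collapse = " + ")))
    lmerTest::lmer(fml, data = df, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE))
  }
  model <- fit_with(keep)
  # remove singular (zero-variance) intercepts and refit
  for (pass in 1:3) {
    if (!inherits(model, "merMod")) break
    vc <- as.data.frame(lme4::VarCorr(model))
    zero <- vc$grp[vc$grp != "Residual" & vc$vcov < 1e-10]
    if (!length(zero)) break
    keep[names(terms) %in% zero] <- FALSE
    dropped <- c(dropped, zero)
    model <- fit_with(keep)
  }
  if (inherits(model, "merMod") && !is.null(model@optinfo$conv$lme4$messages))
    warning("mixed-model convergence messages: ",
            paste(model@optinfo$conv$lme4$messages, collapse = "; "))

  vcomp <- c(patient = 0, eye = 0, box = 0, residual = NA_real_)
  if (inherits(model, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(model))
    for (g in c("patient", "eye", "box")) {
      hit <- vc$vcov[vc$grp == g]
      if (length(hit)) vcomp[g] <- hit
    }
    vcomp["residual"] <- stats::sigma(model)^2
  } else {
    vcomp["residual"] <- stats::sigma(model)^2
  }
  emm <- emmeans::emmeans(model, "visit", lmer.df = "satterthwaite")
  fe <- as.data.frame(emm)
  structure(list(model = model,
                 variance_components = vcomp,
                 fixed_effects = fe,
                 dropped_intercepts = unique(dropped),
                 n_boxes = length(unique(paste(df$eye, df$box_id))),
                 group = group %||% "all",
                 emmeans = emm),
            class = "lmm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise visit contrasts with Tukey adjustment
#'
#' Computes all six pairwise visit contrasts from the fitted model,
#' adjusts p-values over that family with Tukey's studentized-range
#' method (Satterthwaite df), and reports the contrasts of every other
#' visit against the onset visit in the published table layout. CIs are
#' unadjusted 95% intervals alongside the adjusted p-values.
#'
#' @param fit An `lmm_result` from [fit_lmm()].
#' @param reference_visit Visit index treated as onset (default 1).
#' @return A tibble with `comparison`, `visit_index`, `n_boxes`, `emd`,
#'   `ci_low`, `ci_high`, `p_adj`, plus attribute `"all_pairs"` holding
#'   the full 6-contrast family.
#' @export
emd_contrasts <- function(fit, reference_visit = 1L) {
  stopifnot(inherits(fit, "lmm_result"))
  prs <- emmeans::contrast(fit$emmeans, method = "pairwise")
  padj <- as.data.frame(summary(prs, adjust = "tukey"))
  ci <- as.data.frame(stats::confint(prs, level = 0.95, adjust = "none"))
  all_pairs <- data.frame(contrast = padj$contrast,
                          estimate = padj$estimate,
                          ci_low = ci$lower.CL, ci_high = ci$upper.CL,
                          p_adj = padj$p.value)
  lv <- levels(fit$fixed_effects$visit)
  ref <- as.character(reference_visit)
  if (!ref %in% lv) stop("reference visit ", ref, " not in the fit")
  labels <- c("0" = "1 y prior to hyperTD onset",
              "1" = "hyperTD onset",
              "2" = "1 y after hyperTD onset",
              "3" = "2 y after hyperTD onset")
  rows <- lapply(setdiff(lv, ref), function(v) {
    hit <- which(all_pairs$contrast == paste0("visit", v, " - visit", ref))
    sign <- 1
    if (!length(hit)) {
      hit <- which(all_pairs$contrast == paste0("visit", ref, " - visit", v))
      sign <- -1
    }
    stopifnot(length(hit) == 1)
    data.frame(comparison = unname(labels[v]),
               visit_index = as.integer(v),
               n_boxes = fit$n_boxes,
               emd = sign * all_pairs$estimate[hit],
               ci_low = if (sign > 0) all_pairs$ci_low[hit]
                        else -all_pairs$ci_high[hit],
               ci_high = if (sign > 0) all_pairs$ci_high[hit]
                         else -all_pairs$ci_low[hit],
               p_adj = all_pairs$p_adj[hit])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- out[order(out$visit_index), ]
  attr(out, "all_pairs") <- all_pairs
  out
}

#' Group-level summary tables
#'
#' Fits the mixed model per box category — target, all background,
#' adjacent background, non-adjacent background — and reports the
#' published table layout (comparison, n boxes, EMD with 95% CI,
#' adjusted p) for each, as CSVs plus a human-readable report.
#'
#' @param table Pooled box-observation table across eyes.
#' @param out_dir Optional directory for `tables/*.csv` and `report.txt`.
#' @param reference_visit Onset visit index.
#' @return A list of class `ccfd_report`: per-group contrast tibbles
#'   (`target`, `background`, `adjacent`, `nonadjacent`; missing groups
#'   are omitted with a warning) and `fits`.
#' @export
summarize_tables <- function(table, out_dir = NULL, reference_visit = 1L) {
  groups <- c(target = "target", background = "background",
              adjacent = "adjacent_background",
              nonadjacent = "nonadjacent_background")
  fits <- list(); tabs <- list()
  for (nm in names(groups)) {
    res <- tryCatch(fit_lmm(table, group = groups[[nm]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("table for group '", nm, "' omitted: ", conditionMessage(res))
      next
    }
    fits[[nm]] <- res
    tabs[[nm]] <- emd_contrasts(res, reference_visit = reference_visit)
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    for (nm in names(tabs))
      write.csv(tabs[[nm]], file.path(out_dir, "tables",
                                      paste0(nm, "_contrasts.csv")),
                row.names = FALSE)
    writeLines(format_report(tabs), file.path(out_dir, "report.txt"))
  }
  structure(c(tabs, list(fits = fits)), class = "ccfd_report")
}

format_report <- function(tabs) {
  titles <- c(target = "Target boxes",
              background = "All background boxes",
              adjacent = "Adjacent background boxes",
              nonadjacent = "Non-adjacent background boxes")
  out <- c("Mean differences in CCFD% versus the hyperTD onset visit", "")
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    out <- c(out, paste0(titles[nm], " (n = ", tb$n_boxes[1], ")"))
    for (i in seq_len(nrow(tb))) {
      out <- c(out, sprintf(
        "  %-28s EMD = %6.2f%% (95%% CI %6.2f to %6.2f)  p = %s",
        tb$comparison[i], tb$emd[i], tb$ci_low[i], tb$ci_high[i],
        format.pval(tb$p_adj[i], digits = 2, eps = 1e-3)))
    }
    out <- c(out, "")
  }
  out
}

#' @method print ccfd_report
#' @export
print.ccfd_report <- function(x, ...) {
  cat(format_report(x[setdiff(names(x), "fits")]), sep = "\n")
  invisible(x)
}
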