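#' Split a cohort into the study's subgroups
#'
#' Named splits: `"uicc"` (UICC I/II vs III), `"neoadjuvant"` (no vs
#' yes), `"location"` (colon — including synchronous tumours — vs
#' rectum), `"neln12"` (examined nodes >= 12 vs < 12). Always a
#' partition: subgroup sizes sum to the cohort size.
#'
#' @param cohort a cohort (with metrics appended for `"uicc"`).
#' @param selector one of the four split names.
#' @return named list of sub-cohorts (empty parts removed).
#' @export
subgroup_split <- function(cohort, selector) {
  if (!"stage" %in% names(cohort)) cohort <- add_nodal_metrics(cohort)
  key <- switch(selector,
    uicc = ifelse(cohort$stage == "UICC_III", "UICC III", "UICC I/II"),
    neoadjuvant = ifelse(cohort$neoadjuvant == "yes",
                         "neoadjuvant", "no neoadjuvant"),
    location = ifelse(cohort$location == "rectum", "rectum", "colon"),
    neln12 = ifelse(cohort$neln >= 12, "NELN >= 12", "NELN < 12"),
    stop("unknown subgroup selector: ", selector))
  parts <- split(seq_len(nrow(cohort)), key)
  lapply(parts, function(idx) cohort[idx, , drop = FALSE])
}

#' Low/high-risk grouping within stage III
#'
#' High risk: T4 or N2 (or both); low risk: T1, T2, or T3 with N1.
#'
#' @param t_cat T categories.
#' @param n_cat N categories (`"N0"/"N1"/"N2"`).
#' @return character vector `"high"`/`"low"`.
#' @export
risk_group <- function(t_cat, n_cat) {
  ifelse(t_cat == "T4" | n_cat == "N2", "high", "low")
}

#' Export Kaplan-Meier curves per group
#'
#' Plot-ready step coordinates per group plus a log-rank p-value
#' (omitted when fewer than two non-empty groups remain). `grouping` may
#' be a vector of labels, a fitted scheme (records classified on the
#' scheme's variable), or `"risk"` for the stage III low/high-risk rule.
#'
#' @param cohort a cohort with metrics appended.
#' @param grouping vector, `ln_scheme`, or `"risk"`.
#' @return list of class `km_export`: `curves` (named list of step-
#'   coordinate data frames), `logrank` ([logrank_test()] result or
#'   `NULL`), `omitted` (labels of empty groups).
#' @export
export_km <- function(cohort, grouping) {
  if (!"n_cat" %in% names(cohort)) cohort <- add_nodal_metrics(cohort)
  if (inherits(grouping, "ln_scheme")) {
    v <- if (grouping$variable == "LNR") cohort$lnr else cohort$lodds
    idx <- classify(v, grouping)
    labels <- factor(grouping$classes$label[idx],
                     levels = grouping$classes$label)
  } else if (identical(grouping, "risk")) {
    labels <- factor(risk_group(cohort$t_cat, cohort$n_cat),
                     levels = c("low", "high"))
  } else {
    stopifnot(length(grouping) == nrow(cohort))
    labels <- as.factor(grouping)
  }
  omitted <- levels(labels)[table(labels) == 0]
  labels <- droplevels(labels)
  curves <- lapply(levels(labels), function(lv) {
    sel <- labels == lv
    km <- km_estimate(cohort$time_months[sel], cohort$event[sel])
    data.frame(time = c(0, km$time), surv = c(1, km$surv),
               n_risk = c(sum(sel), km$n_risk),
               n_event = c(0, km$n_event), n_censor = c(0, km$n_censor))
  })
  names(curves) <- levels(labels)
  lr <- if (nlevels(labels) >= 2)
    logrank_test(cohort$time_months, cohort$event, labels) else NULL
  structure(list(curves = curves, logrank = lr, omitted = omitted),
            class = "km_export")
}

# classify a cohort under a scheme, merging classes left empty in this
# cohort upward into the adjacent lower class; returns the class factor
# (labels kept for occupied classes) plus merge notes
.classify_merged <- function(cohort, scheme) {
  v <- if (scheme$variable == "LNR") cohort$lnr else cohort$lodds
  idx <- as.integer(classify(v, scheme))
  k <- nrow(scheme$classes)
  occupied <- sort(unique(idx))
  notes <- character(0)
  if (length(occupied) < k) {
    empty <- setdiff(seq_len(k), occupied)
    notes <- sprintf("class %d ('%s') empty: merged into adjacent class",
                     empty, scheme$classes$label[empty])
    # collapse the index scale over occupied classes only
  }
  merged <- match(idx, occupied)
  list(class_index = merged,
       labels = scheme$classes$label[occupied],
       notes = notes)
}

# indicator contrasts against the first (reference) class
.class_indicators <- function(class_index, labels, prefix) {
  k <- length(labels)
  if (k < 2) return(NULL)
  m <- vapply(2:k, function(j) as.numeric(class_index == j),
              numeric(length(class_index)))
  m <- matrix(m, ncol = k - 1)
  colnames(m) <- paste0(prefix, ": ", labels[2:k])
  m
}

#' Run the full classification-system comparison
#'
#' End to end: filter (when exclusion flags are present), impute, append
#' nodal metrics, fit the cohort-quantile LODDS scheme on the analysis
#' cohort, then within every requested subgroup fit the adjusted base
#' model plus (a) AJCC N-category indicators — the reference model — and
#' (b) each scheme's class indicators, compute Harrell's C on each
#' model's linear predictor with a jackknife CI, the jackknife Delta C
#' of each scheme against the N-category model, and Benjamini-Hochberg
#' FDR over the scheme family within the subgroup. Classes left empty in
#' a subgroup are merged into the adjacent lower class with a note;
#' subgroups without events are skipped with a notice. Landmark ROC AUCs
#' at the requested horizons are computed on the full analysis cohort
#' for the continuous metrics (LODDS, LNR, positive and examined node
#' counts) and for each scheme's class index. Deterministic given the
#' input cohort.
#'
#' @param cohort a cohort (raw or analysis-ready).
#' @param schemes named list of schemes, default [builtin_schemes()]
#'   (the quantile spec is fitted on the analysis cohort).
#' @param subgroups subset of
#'   `c("all", "uicc", "neoadjuvant", "location", "neln12")`.
#' @param horizons landmark horizons in months, default `c(12, 36, 60)`.
#' @param out_dir optional directory: writes `comparison.csv`,
#'   `class_hr.csv`, `auc.csv` and `manifest.json`.
#' @return object of class `ln_analysis`: `comparison` (one row per
#'   scheme per subgroup, N-category reference rows flagged),
#'   `class_hr` (per-class hazard ratios), `auc` (landmark AUC table),
#'   `exclusion_tally`, `notes` (merge/skip/convergence messages),
#'   `schemes` (the fitted scheme list).
#' @export
run_full_analysis <- function(cohort, schemes = builtin_schemes(),
                              subgroups = c("all", "uicc"),
                              horizons = c(12, 36, 60),
                              out_dir = NULL) {
  stopifnot(length(schemes) >= 1, all(horizons > 0))
  notes <- character(0)
  tally <- NULL
  if (any(vapply(.flag_cols, function(fc) any(cohort[[fc]]), logical(1)))) {
    f <- filter_cohort(cohort)
    cohort <- f$cohort
    tally <- f$tally
  }
  cohort <- impute_missing(cohort)
  cohort <- add_nodal_metrics(cohort)

  # quantile scheme: fitted once on the analysis cohort, not per subgroup
  schemes <- lapply(schemes, function(s) {
    if (s$kind == "quantile" && is.null(s$classes))
      fit_quantile_scheme(cohort$lodds,
                          probabilities = s$probabilities %||%
                            c(0.25, 0.5, 0.75),
                          name = s$name)
    else s
  })

  parts <- list()
  for (sg in subgroups) {
    if (sg == "all") parts[["all"]] <- list(cohort = cohort)
    else for (nm in names(sp <- subgroup_split(cohort, sg)))
      parts[[paste0(sg, ": ", nm)]] <- list(cohort = sp[[nm]])
  }

  comparison <- list(); class_hr <- list()
  for (part_name in names(parts)) {
    part <- parts[[part_name]]$cohort
    if (sum(part$event) == 0) {
      notes <- c(notes, paste0("subgroup '", part_name,
                               "' skipped: no events"))
      next
    }
    x_base <- encode_covariates(part)  # size median per analysis cohort
    tm <- part$time_months; ev <- part$event

    # reference model: base + N-category indicators (first present
    # category is the reference class)
    n_fac <- factor(part$n_cat, levels = c("N0", "N1", "N2"))
    n_fac <- droplevels(n_fac)
    n_ind <- .class_indicators(as.integer(n_fac), levels(n_fac),
                               "N category")
    fit_ref <- cox_fit(cbind(x_base, n_ind), tm, ev)
    if (!is.null(fit_ref$flagged))
      notes <- c(notes, paste0(part_name, " / N category: ",
                               paste(fit_ref$flagged, collapse = "; ")))
    c_ref <- jackknife_c_se(fit_ref$linear_predictor, tm, ev)
    comparison[[length(comparison) + 1]] <- data.frame(
      subgroup = part_name, scheme = "N category", reference = TRUE,
      n = nrow(part), events = sum(ev),
      c_index = c_ref$c_index, c_low = c_ref$ci_low,
      c_high = c_ref$ci_high, delta_c = 0, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
      p_fdr = NA_real_, notes = "", stringsAsFactors = FALSE)
    class_hr[[length(class_hr) + 1]] <- .hr_rows(part_name, "N category",
                                                 levels(n_fac), fit_ref,
                                                 "N category")

    rows <- list()
    for (s in schemes) {
      cm <- .classify_merged(part, s)
      if (length(cm$notes) > 0)
        notes <- c(notes, paste0(part_name, " / ", s$name, ": ",
                                 cm$notes))
      ind <- .class_indicators(cm$class_index, cm$labels, s$name)
      if (is.null(ind)) {
        notes <- c(notes, paste0(part_name, " / ", s$name,
                                 ": single occupied class, skipped"))
        next
      }
      fit_s <- cox_fit(cbind(x_base, ind), tm, ev)
      if (!is.null(fit_s$flagged))
        notes <- c(notes, paste0(part_name, " / ", s$name, ": ",
                                 paste(fit_s$flagged, collapse = "; ")))
      c_s <- jackknife_c_se(fit_s$linear_predictor, tm, ev)
      dc <- jackknife_delta_c(fit_s$linear_predictor,
                              fit_ref$linear_predictor, tm, ev)
      rows[[length(rows) + 1]] <- data.frame(
        subgroup = part_name, scheme = s$name, reference = FALSE,
        n = nrow(part), events = sum(ev),
        c_index = c_s$c_index, c_low = c_s$ci_low, c_high = c_s$ci_high,
        delta_c = dc$delta_c, se = dc$se, ci_low = dc$ci_low,
        ci_high = dc$ci_high, p = dc$p_value, p_fdr = NA_real_,
        notes = paste(cm$notes, collapse = "; "),
        stringsAsFactors = FALSE)
      class_hr[[length(class_hr) + 1]] <- .hr_rows(part_name, s$name,
                                                   cm$labels, fit_s,
                                                   s$name)
    }
    if (length(rows) > 0) {
      block <- do.call(rbind, rows)
      # FDR family: the schemes compared against N within this subgroup
      block$p_fdr <- fdr_adjust(block$p)
      comparison[[length(comparison) + 1]] <- block
    }
  }
  comparison <- do.call(rbind, comparison)
  rownames(comparison) <- NULL
  class_hr <- do.call(rbind, class_hr)
  rownames(class_hr) <- NULL

  auc <- .landmark_table(cohort, schemes, horizons)

  res <- structure(list(comparison = comparison, class_hr = class_hr,
                        auc = auc, exclusion_tally = tally, notes = notes,
                        schemes = schemes, cohort_n = nrow(cohort),
                        cohort_events = sum(cohort$event)),
                   class = "ln_analysis")
  if (!is.null(out_dir)) .write_analysis(res, out_dir)
  res
}

# per-class HR rows in the reference-class layout of published reports
.hr_rows <- function(subgroup, scheme_name, labels, fit, prefix) {
  ref <- data.frame(subgroup = subgroup, scheme = scheme_name,
                    class = labels[1], hr = 1, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(labels) < 2 || is.null(fit$hr)) return(ref)
  want <- paste0(prefix, ": ", labels[-1])
  tab <- fit$hr[match(want, fit$hr$term), , drop = FALSE]
  rbind(ref, data.frame(subgroup = subgroup, scheme = scheme_name,
                        class = labels[-1], hr = tab$hr,
                        ci_low = tab$ci_low, ci_high = tab$ci_high,
                        p = tab$p, stringsAsFactors = FALSE))
}

.landmark_table <- function(cohort, schemes, horizons) {
  scores <- list(LODDS = cohort$lodds, LNR = cohort$lnr,
                 pLN = cohort$pln, tLN = -cohort$neln)
  for (s in schemes) {
    v <- if (s$variable == "LNR") cohort$lnr else cohort$lodds
    scores[[paste0(s$name, " (classes)")]] <-
      as.integer(classify(v, s))
  }
  rows <- list()
  for (h in horizons) for (nm in names(scores)) {
    a <- tryCatch(landmark_auc(scores[[nm]], cohort$time_months,
                               cohort$event, h),
                  error = function(e) NULL)
    if (is.null(a)) next
    rows[[length(rows) + 1]] <- data.frame(
      horizon = h, score = nm, auc = a$auc, n_cases = a$n_cases,
      n_controls = a$n_controls, n_excluded = a$n_excluded,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(res$class_hr, file.path(out_dir, "class_hr.csv"),
                   row.names = FALSE)
  if (!is.null(res$auc))
    utils::write.csv(res$auc, file.path(out_dir, "auc.csv"),
                     row.names = FALSE)
  manifest <- list(cohort_n = res$cohort_n,
                   cohort_events = res$cohort_events,
                   exclusion_tally = as.list(res$exclusion_tally),
                   schemes = names(res$schemes), notes = res$notes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ln_analysis <- function(x, digits = 4, ...) {
  cat("lymph node classification comparison: ", x$cohort_n,
      " subjects, ", x$cohort_events, " events\n\n", sep = "")
  tab <- x$comparison
  tab$c_index <- round(tab$c_index, digits)
  tab$delta_c <- round(tab$delta_c, digits)
  tab$p_fdr <- signif(tab$p_fdr, 3)
  print(tab[, c("subgroup", "scheme", "n", "events", "c_index",
                "delta_c", "p_fdr")], row.names = FALSE)
  if (length(x$notes) > 0)
    cat("\nnotes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
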