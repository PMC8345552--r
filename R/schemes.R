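#' Construct an interval-based lymph node classification scheme
#'
#' A scheme is a named, ordered partition of the LNR axis (\[0, 1\]) or
#' the LODDS axis (the whole real line) into interval classes. Class 1 is
#' always the prognostic reference class. Interval bounds may be open or
#' closed; consecutive classes must share a boundary with complementary
#' closure so the union covers the attainable range with no overlap.
#'
#' @param name scheme name (used in reports and lookups).
#' @param variable `"LNR"` or `"LODDS"`.
#' @param classes data frame with columns `label` (character), `lower`,
#'   `upper` (numeric, `-Inf`/`Inf` allowed) and logical `lower_closed`,
#'   `upper_closed`.
#' @param source citation tag for the published cut-offs.
#' @param kind `"fixed"` (published cut-offs) or `"quantile"`
#'   (cohort-fitted percentile cut-offs).
#' @param log_base for LODDS schemes, the log base the cut-offs assume
#'   (default `"natural"`).
#' @param repairs character vector describing any repairs applied to the
#'   printed cut-offs (rounding gaps, sign slips); surfaced in reports.
#' @return object of class `ln_scheme`.
#' @export
new_scheme <- function(name, variable, classes, source = "user",
                       kind = "fixed", log_base = "natural",
                       repairs = character(0)) {
  variable <- match.arg(variable, c("LNR", "LODDS"))
  kind <- match.arg(kind, c("fixed", "quantile"))
  stopifnot(is.data.frame(classes),
            all(c("label", "lower", "upper", "lower_closed",
                  "upper_closed") %in% names(classes)))
  s <- structure(list(name = name, source = source, variable = variable,
                      classes = classes, kind = kind, log_base = log_base,
                      repairs = repairs),
                 class = "ln_scheme")
  validate_scheme(s)
  s
}

# shorthand: build the classes frame from interleaved bounds
.classes <- function(labels, lower, lower_closed, upper, upper_closed) {
  data.frame(label = labels, lower = lower, lower_closed = lower_closed,
             upper = upper, upper_closed = upper_closed,
             stringsAsFactors = FALSE)
}

#' Validate a classification scheme
#'
#' Checks that classes are increasing, non-overlapping, gap-free
#' (consecutive classes share a boundary with exactly one side closed)
#' and that their union covers the variable's attainable range: \[0, 1\]
#' for LNR, all reals for LODDS.
#'
#' @param s an `ln_scheme`.
#' @return invisibly `TRUE`; stops citing the offending class pair.
#' @export
validate_scheme <- function(s) {
  cl <- s$classes
  if (nrow(cl) < 2) stop("scheme '", s$name, "': needs >= 2 classes")
  for (k in seq_len(nrow(cl))) {
    if (!(cl$lower[k] < cl$upper[k] ||
          (cl$lower[k] == cl$upper[k] && cl$lower_closed[k] &&
           cl$upper_closed[k])))
      stop("scheme '", s$name, "': class ", k, " ('", cl$label[k],
           "') has empty interval")
  }
  for (k in seq_len(nrow(cl) - 1)) {
    if (cl$upper[k] != cl$lower[k + 1])
      stop("scheme '", s$name, "': classes ", k, " and ", k + 1,
           " ('", cl$label[k], "' / '", cl$label[k + 1], "') ",
           if (cl$upper[k] > cl$lower[k + 1]) "overlap" else "leave a gap")
    if (cl$upper_closed[k] == cl$lower_closed[k + 1])
      stop("scheme '", s$name, "': boundary ", cl$upper[k],
           " between classes ", k, " and ", k + 1,
           if (cl$upper_closed[k]) " is claimed by both" else
             " is claimed by neither")
  }
  lo_ok <- if (s$variable == "LNR")
    cl$lower[1] <= 0 && (cl$lower[1] < 0 || cl$lower_closed[1])
  else is.infinite(cl$lower[1]) && cl$lower[1] < 0
  hi <- nrow(cl)
  hi_ok <- if (s$variable == "LNR")
    cl$upper[hi] >= 1 && (cl$upper[hi] > 1 || cl$upper_closed[hi])
  else is.infinite(cl$upper[hi]) && cl$upper[hi] > 0
  if (!lo_ok || !hi_ok)
    stop("scheme '", s$name, "': classes do not cover the attainable ",
         "range of ", s$variable)
  invisible(TRUE)
}

#' Built-in classification schemes
#'
#' The seven published fixed-cut-off schemes that showed superior
#' stage III discrimination in the source study (two LNR, five LODDS),
#' plus the cohort-quantile LODDS specification (25/50/75th percentiles,
#' to be fitted on an analysis cohort with [fit_quantile_scheme()]).
#'
#' Two printed cut-off sets required repair, recorded in each scheme's
#' `repairs` field: the Fortea-Sanchis LNR classes are printed with a
#' rounding gap between 0.24 and 0.25 (closed here at a 0.25 boundary),
#' and the third Bagante LODDS class is printed with lower bound ">0.9"
#' which would leave (-0.9, 0.9\] unassigned — read as a sign slip for
#' ">-0.9".
#'
#' @return named list of `ln_scheme` objects (the quantile entry is the
#'   unfitted specification, `kind = "quantile"`).
#' @export
builtin_schemes <- function() {
  s <- list(
    new_scheme("LNR Lee", "LNR", .classes(
      c(">=0; <=0.1", ">0.1; <=0.2", ">0.2; <=0.3", ">0.3"),
      lower = c(0, 0.1, 0.2, 0.3), lower_closed = c(TRUE, FALSE, FALSE, FALSE),
      upper = c(0.1, 0.2, 0.3, 1), upper_closed = c(TRUE, TRUE, TRUE, TRUE)),
      source = "Lee et al."),
    new_scheme("LNR Fortea-Sanchis", "LNR", .classes(
      c("0; 0.24", "0.25; 0.60", ">0.60"),
      lower = c(0, 0.25, 0.60), lower_closed = c(TRUE, TRUE, FALSE),
      upper = c(0.25, 0.60, 1), upper_closed = c(FALSE, TRUE, TRUE)),
      source = "Fortea-Sanchis et al.",
      repairs = "printed gap (0.24, 0.25) read as a rounded 0.25 boundary"),
    new_scheme("LODDS Fortea-Sanchis", "LODDS", .classes(
      c("<-2", ">=-2; <=-1", ">-1"),
      lower = c(-Inf, -2, -1), lower_closed = c(FALSE, TRUE, FALSE),
      upper = c(-2, -1, Inf), upper_closed = c(FALSE, TRUE, FALSE)),
      source = "Fortea-Sanchis et al."),
    new_scheme("LODDS He", "LODDS", .classes(
      c("<-3", ">=-3; <-2", ">=-2; <-1", ">=-1; <0", ">=0"),
      lower = c(-Inf, -3, -2, -1, 0),
      lower_closed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
      upper = c(-3, -2, -1, 0, Inf),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE)),
      source = "He et al."),
    new_scheme("LODDS Calero", "LODDS", .classes(
      c("<=-3", ">-3; <=-1", ">-1; <=3", ">3"),
      lower = c(-Inf, -3, -1, 3), lower_closed = c(FALSE, FALSE, FALSE, FALSE),
      upper = c(-3, -1, 3, Inf), upper_closed = c(TRUE, TRUE, TRUE, FALSE)),
      source = "Calero et al."),
    new_scheme("LODDS Bagante", "LODDS", .classes(
      c("<-2", ">=-2; <=-0.9", ">-0.9; <=1.5", ">1.5"),
      lower = c(-Inf, -2, -0.9, 1.5),
      lower_closed = c(FALSE, TRUE, FALSE, FALSE),
      upper = c(-2, -0.9, 1.5, Inf),
      upper_closed = c(FALSE, TRUE, TRUE, FALSE)),
      source = "Bagante et al.",
      repairs = "printed class-3 lower bound '>0.9' read as sign slip for '>-0.9'"),
    new_scheme("LODDS Jian-Hui", "LODDS", .classes(
      c("<=-1.5", ">-1.5; <=-1", ">-1; <=0", ">0"),
      lower = c(-Inf, -1.5, -1, 0), lower_closed = c(FALSE, FALSE, FALSE, FALSE),
      upper = c(-1.5, -1, 0, Inf), upper_closed = c(TRUE, TRUE, TRUE, FALSE)),
      source = "Jian-Hui et al.")
  )
  names(s) <- vapply(s, `[[`, "", "name")
  s[["LODDS quantile"]] <- structure(
    list(name = "LODDS quantile", source = "cohort quantiles",
         variable = "LODDS", classes = NULL, kind = "quantile",
         log_base = "natural", repairs = character(0),
         probabilities = c(0.25, 0.50, 0.75)),
    class = "ln_scheme")
  s
}

#' Classify a value under a scheme
#'
#' Returns the 1-based index of the unique class containing each value;
#' errors if any value falls outside every class (unreachable for the
#' shipped schemes, whose classes cover the attainable range).
#'
#' @param value numeric vector of LNR or LODDS values.
#' @param scheme a fitted `ln_scheme` (i.e. with `classes`).
#' @return integer vector of class indices, with the matching labels as
#'   a `"labels"` attribute.
#' @export
classify <- function(value, scheme) {
  cl <- scheme$classes
  if (is.null(cl))
    stop("scheme '", scheme$name, "' is an unfitted quantile spec; ",
         "call fit_quantile_scheme() first")
  idx <- rep(NA_integer_, length(value))
  for (k in seq_len(nrow(cl))) {
    in_k <- (value > cl$lower[k] | (cl$lower_closed[k] & value == cl$lower[k])) &
      (value < cl$upper[k] | (cl$upper_closed[k] & value == cl$upper[k]))
    idx[is.na(idx) & in_k] <- k
  }
  if (anyNA(idx))
    stop("scheme '", scheme$name, "': value(s) ",
         paste(utils::head(value[is.na(idx)], 5), collapse = ", "),
         " fall outside every class")
  structure(idx, labels = cl$label[idx])
}

#' Fit the cohort-quantile LODDS scheme
#'
#' Cut points at the empirical 25th/50th/75th percentiles of the supplied
#' LODDS values (linear interpolation between order statistics, R
#' `quantile` type 7). Classes are half-open `[q_{k-1}, q_k)` with the
#' first open below at `-Inf` and the last closed up to `+Inf`.
#'
#' @param values LODDS values of the analysis cohort (>= 4 distinct).
#' @param probabilities strictly increasing cut probabilities in (0, 1);
#'   default `c(0.25, 0.5, 0.75)`.
#' @param name scheme name for reports.
#' @return fitted `ln_scheme` of kind `"quantile"`.
#' @export
fit_quantile_scheme <- function(values, probabilities = c(0.25, 0.5, 0.75),
                                name = "LODDS quantile") {
  stopifnot(all(diff(probabilities) > 0), all(probabilities > 0),
            all(probabilities < 1))
  if (length(unique(values)) < 4)
    stop("need >= 4 distinct values to fit quantile cut-offs")
  q <- unname(stats::quantile(values, probabilities, type = 7))
  if (anyDuplicated(q))
    stop("non-distinct quantiles: cut points ",
         paste(signif(q, 6), collapse = ", "))
  k <- length(q)
  cl <- .classes(
    labels = c(paste0("<", signif(q[1], 4)),
               paste0("[", signif(q[-k], 4), "; ", signif(q[-1], 4), ")"),
               paste0(">=", signif(q[k], 4))),
    lower = c(-Inf, q), lower_closed = c(FALSE, rep(TRUE, k)),
    upper = c(q, Inf), upper_closed = rep(FALSE, k + 1))
  s <- new_scheme(name, "LODDS", cl, source = "cohort quantiles",
                  kind = "quantile")
  s$probabilities <- probabilities
  s$cut_points <- q
  s$percentile_definition <- "linear interpolation (type 7)"
  s
}

#' Load classification schemes from a JSON config
#'
#' Each config entry mirrors the scheme fields: `name`, `source`,
#' `variable`, `log_base`, and a `classes` array of
#' `{label, lower, lower_closed, upper, upper_closed}` (`"-Inf"`/`"Inf"`
#' accepted for unbounded sides). Schemes are validated against the same
#' invariants as the built-ins; a printed gap between consecutive classes
#' is only accepted when the entry carries `"repair": "extend_left"`,
#' which moves the later class's lower bound down to close the gap.
#'
#' @param path JSON file with a top-level array of scheme entries.
#' @return named list of `ln_scheme` objects.
#' @export
load_schemes <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)  # single entry, not wrapped
  out <- list()
  for (entry in raw) {
    cl <- do.call(rbind, lapply(entry$classes, function(e)
      data.frame(label = e$label,
                 lower = .num_bound(e$lower), upper = .num_bound(e$upper),
                 lower_closed = isTRUE(e$lower_closed),
                 upper_closed = isTRUE(e$upper_closed),
                 stringsAsFactors = FALSE)))
    cl <- cl[order(cl$lower), c("label", "lower", "lower_closed",
                                "upper", "upper_closed")]
    rownames(cl) <- NULL
    repairs <- character(0)
    if (identical(entry$repair, "extend_left")) {
      for (k in seq_len(nrow(cl) - 1)) {
        if (cl$upper[k] < cl$lower[k + 1]) {
          repairs <- c(repairs, sprintf(
            "gap (%g, %g) closed by extend_left", cl$upper[k],
            cl$lower[k + 1]))
          cl$lower[k + 1] <- cl$upper[k]
          cl$lower_closed[k + 1] <- !cl$upper_closed[k]
        }
      }
    }
    out[[entry$name]] <- new_scheme(
      entry$name, entry$variable, cl,
      source = entry$source %||% "config",
      log_base = entry$log_base %||% "natural",
      repairs = repairs)
  }
  out
}

.num_bound <- function(x) {
  if (is.character(x)) {
    if (x %in% c("Inf", "+Inf")) return(Inf)
    if (x == "-Inf") return(-Inf)
    return(as.numeric(x))
  }
  as.numeric(x)
}

#' Serialise schemes to the JSON config format
#'
#' Round-trip partner of [load_schemes()].
#'
#' @param schemes list of `ln_scheme` objects.
#' @param path output JSON path.
#' @return invisibly `path`.
#' @export
write_schemes <- function(schemes, path) {
  enc <- lapply(schemes, function(s) {
    list(name = s$name, source = s$source, variable = s$variable,
         log_base = s$log_base,
         classes = lapply(seq_len(nrow(s$classes)), function(k) {
           cl <- s$classes[k, ]
           list(label = cl$label,
                lower = if (is.finite(cl$lower)) cl$lower else
                  as.character(cl$lower),
                lower_closed = cl$lower_closed,
                upper = if (is.finite(cl$upper)) cl$upper else
                  as.character(cl$upper),
                upper_closed = cl$upper_closed)
         }))
  })
  jsonlite::write_json(unname(enc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.ln_scheme <- function(x, ...) {
  cat("scheme '", x$name, "' (", x$variable, ", ", x$kind, ", source: ",
      x$source, ")\n", sep = "")
  if (is.null(x$classes)) {
    cat("  unfitted quantile spec, probabilities ",
        paste(x$probabilities, collapse = "/"), "\n", sep = "")
  } else {
    for (k in seq_len(nrow(x$classes)))
      cat(sprintf("  %d%s %s\n", k, if (k == 1) " (ref)" else "",
                  x$classes$label[k]))
  }
  if (length(x$repairs))
    cat("  repairs: ", paste(x$repairs, collapse = "; "), "\n", sep = "")
  invisible(x)
}
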