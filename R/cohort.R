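# Declared category orders; mode ties in imputation break towards the
# first listed level, and factors built from these columns use this order.
.lnstage_levels <- list(
  sex         = c("male", "female"),
  t_cat       = c("T1", "T2", "T3", "T4"),
  grade       = c("G1", "G2", "G3", "G4", "unknown"),
  location    = c("caecum", "ascending", "transverse", "descending",
                  "sigmoid", "rectum", "synchronous"),
  neoadjuvant = c("no", "yes")
)

# Exclusion criteria in the order the study lists them; a record with
# several flags set is tallied once, under the earliest listed criterion.
.exclusion_order <- c("metastatic", "incomplete_histopath", "margin_positive",
                      "death_within_30d", "emergency", "lost_followup",
                      "polyposis_or_ibd")
.flag_cols <- paste0("excl_", .exclusion_order)

.core_cols <- c("id", "time_months", "event", "age", "sex", "neln", "pln",
                "t_cat", "grade", "size_mm", "location", "neoadjuvant")

#' Construct a patient cohort
#'
#' A cohort is a data frame of patient records with one row per subject:
#' survival time in months, a death indicator, examined (`neln`) and
#' positive (`pln`) lymph node counts, baseline covariates, an optional
#' N1c tumor-deposit flag, and one boolean column per exclusion criterion
#' (`excl_metastatic`, `excl_incomplete_histopath`, `excl_margin_positive`,
#' `excl_death_within_30d`, `excl_emergency`, `excl_lost_followup`,
#' `excl_polyposis_or_ibd`). Missing covariate values are `NA`; structural
#' fields (`id`, `time_months`, `event`, `neln`, `pln`) must be complete.
#'
#' @param df data frame with at least the core columns
#'   `id, time_months, event, age, sex, neln, pln, t_cat, grade, size_mm,
#'   location, neoadjuvant`. Missing flag columns are added as `FALSE`;
#'   a missing `n1c` column is added as `FALSE`.
#' @param provenance character tag recording where the rows came from
#'   (file path or generator seed).
#' @return object of class `cohort` (a data frame).
#' @export
as_cohort <- function(df, provenance = "constructed") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.core_cols, names(df))
  if (length(missing_cols) > 0)
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"n1c" %in% names(df)) df$n1c <- FALSE
  for (fc in .flag_cols) if (!fc %in% names(df)) df[[fc]] <- FALSE
  df$id <- as.character(df$id)
  for (col in names(.lnstage_levels))
    df[[col]] <- as.character(df[[col]])
  df$n1c <- as.logical(df$n1c)
  for (fc in .flag_cols) df[[fc]] <- as.logical(df[[fc]])
  validate_cohort(df)
  structure(df, class = c("cohort", "data.frame"),
            provenance = provenance)
}

#' Validate cohort invariants
#'
#' Checks per-record invariants: positive time, event in \{0,1\},
#' `neln >= 1`, `0 <= pln <= neln`, unique ids, known factor levels.
#' Stops with the offending id(s) on violation.
#'
#' @param df cohort data frame.
#' @return invisibly `TRUE`.
#' @export
validate_cohort <- function(df) {
  if (nrow(df) == 0) stop("empty cohort")
  if (anyDuplicated(df$id))
    stop("duplicate patient ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond))
      stop(msg, " for id(s): ",
           paste(utils::head(df$id[cond], 5), collapse = ", "))
  }
  bad(!(df$time_months > 0), "non-positive survival time")
  bad(!(df$event %in% c(0, 1)), "event indicator not in {0,1}")
  bad(!(df$neln >= 1), "neln < 1")
  bad(df$pln < 0 | df$pln > df$neln, "pln > neln (or negative)")
  for (col in names(.lnstage_levels)) {
    v <- df[[col]]
    ok <- is.na(v) | v %in% .lnstage_levels[[col]]
    if (!all(ok))
      stop("unknown ", col, " value(s): ",
           paste(unique(v[!ok]), collapse = ", "),
           " for id(s): ", paste(utils::head(df$id[!ok], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a cohort from CSV
#'
#' The file must carry the documented header (see [as_cohort()]); missing
#' cells are empty strings. In strict mode (default) any invalid row
#' aborts the read with a row-indexed error; in lenient mode invalid rows
#' are dropped with a summarising warning.
#'
#' @param path CSV file path.
#' @param strict abort on first invalid row (`TRUE`) or drop invalid rows
#'   with a warning (`FALSE`).
#' @return a [cohort][as_cohort].
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.core_cols, names(df))
  if (length(missing_cols) > 0)
    stop("header does not match cohort schema; missing: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("empty cohort")
  row_ok <- rep(TRUE, nrow(df))
  problems <- character(0)
  check <- function(cond, what) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      row_ok[cond] <<- FALSE
      problems <<- c(problems, paste0(
        what, " in row(s) ", paste(which(cond), collapse = ", "),
        " (id: ", paste(df$id[cond], collapse = ", "), ")"))
    }
  }
  check(is.na(df$time_months) | !(suppressWarnings(
    as.numeric(df$time_months)) > 0), "non-positive or unparseable time")
  check(!(df$event %in% c(0, 1)), "event not in {0,1}")
  check(is.na(df$neln) | df$neln < 1, "neln < 1 or missing")
  check(is.na(df$pln) | df$pln < 0, "pln missing or negative")
  valid_nodes <- !is.na(df$pln) & !is.na(df$neln)
  check(valid_nodes & df$pln > df$neln, "pln > neln")
  if (any(!row_ok)) {
    if (strict)
      stop("invalid rows: ", paste(problems, collapse = "; "))
    warning(sum(!row_ok), " invalid row(s) skipped: ",
            paste(problems, collapse = "; "))
    df <- df[row_ok, , drop = FALSE]
    if (nrow(df) == 0) stop("empty cohort")
  }
  as_cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: UTF-8, missing cells as empty strings.
#'
#' @param cohort a cohort.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the study's exclusion filters
#'
#' Removes every record with any exclusion flag set and tallies excluded
#' records per criterion, in the study's listed order: metastatic disease,
#' incomplete histopathological information, positive resection margins,
#' death within 30 days of surgery, emergency surgery, lost to follow-up,
#' polyposis syndromes / inflammatory bowel disease. A record with several
#' flags is counted once, under the earliest listed criterion, so the
#' retained count plus the tally sum always equals the input size.
#'
#' @param cohort a cohort with populated exclusion flags.
#' @return list with elements `cohort` (retained records) and `tally`
#'   (named integer vector over the seven criteria).
#' @export
filter_cohort <- function(cohort) {
  flags <- as.matrix(as.data.frame(cohort)[, .flag_cols, drop = FALSE])
  any_flag <- rowSums(flags) > 0
  # first TRUE flag in listed order, per excluded record
  first_flag <- apply(flags, 1L, function(r) which(r)[1])
  tally <- stats::setNames(integer(length(.exclusion_order)),
                           .exclusion_order)
  if (any(any_flag)) {
    tab <- table(factor(.exclusion_order[unlist(first_flag[any_flag])],
                        levels = .exclusion_order))
    tally[] <- as.integer(tab)
  }
  retained <- cohort[!any_flag, , drop = FALSE]
  if (nrow(retained) == 0) stop("empty cohort after filtering")
  attr(retained, "provenance") <- attr(cohort, "provenance")
  list(cohort = retained, tally = tally)
}

#' Impute missing covariates
#'
#' Single imputation as used in the study: continuous covariates (`age`,
#' `size_mm`) get the column median of observed values; categorical
#' covariates (`sex`, `t_cat`, `grade`, `location`, `neoadjuvant`) get the
#' modal category. Median of an even count is the mean of the two central
#' values. Modal ties break deterministically towards the first level in
#' the declared category order (see the schema). Structural columns
#' (`time_months`, `event`, `neln`, `pln`) are never imputed.
#'
#' @param cohort a cohort.
#' @return cohort with no missing covariate values.
#' @export
impute_missing <- function(cohort) {
  for (col in c("age", "size_mm")) {
    v <- cohort[[col]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0) stop("column entirely missing: ", col)
      cohort[[col]][is.na(v)] <- stats::median(obs)
    }
  }
  for (col in names(.lnstage_levels)) {
    v <- cohort[[col]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0) stop("column entirely missing: ", col)
      counts <- table(factor(obs, levels = .lnstage_levels[[col]]))
      mode_cat <- names(counts)[which.max(counts)]  # ties: first declared
      cohort[[col]][is.na(v)] <- mode_cat
    }
  }
  cohort
}

#' Derive UICC stage for non-metastatic records
#'
#' Stage III when any lymph node is positive or the N1c tumor-deposit
#' flag is set; otherwise stage I for T1/T2 and stage II for T3/T4.
#' Vectorised.
#'
#' @param t_cat T category, one of `"T1".."T4"`.
#' @param pln count of positive lymph nodes.
#' @param n1c logical N1c tumor-deposit flag (default `FALSE`).
#' @return character vector over `{"UICC_I", "UICC_II", "UICC_III"}`.
#' @export
derive_stage <- function(t_cat, pln, n1c = FALSE) {
  n <- max(length(t_cat), length(pln))
  t_cat <- rep_len(t_cat, n); pln <- rep_len(pln, n)
  n1c <- rep_len(n1c, n)
  stopifnot(all(t_cat %in% .lnstage_levels$t_cat), all(pln >= 0))
  ifelse(pln >= 1 | n1c, "UICC_III",
         ifelse(t_cat %in% c("T1", "T2"), "UICC_I", "UICC_II"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", nrow(x), " records, ", sum(x$event), " events",
      " (provenance: ", attr(x, "provenance") %||% "unknown", ")\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep cohort class through row subsetting
#' @export
`[.cohort` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.core_cols %in% names(out))) {
    class(out) <- c("cohort", "data.frame")
    attr(out, "provenance") <- attr(x, "provenance")
  }
  out
}
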