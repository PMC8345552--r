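#' Lymph node ratio
#'
#' LNR = positive lymph nodes / examined lymph nodes. Defined for any
#' record with at least one examined node; lies in \[0, 1\].
#'
#' @param pln positive lymph node count(s), `0 <= pln <= neln`.
#' @param neln examined lymph node count(s), `>= 1`.
#' @return numeric vector of ratios.
#' @export
compute_lnr <- function(pln, neln) {
  stopifnot(length(pln) == length(neln) || length(pln) == 1 ||
              length(neln) == 1)
  if (any(neln < 1)) stop("neln must be >= 1")
  if (any(pln < 0 | pln > neln)) stop("pln must satisfy 0 <= pln <= neln")
  pln / neln
}

#' Log odds of positive lymph nodes
#'
#' LODDS = ln((pln + 0.5) / (neln - pln + 0.5)), the empirical-logistic
#' transform of the positive-node fraction. The 0.5 continuity terms keep
#' the value finite when no node, or every node, is positive, which is
#' exactly where LNR saturates at 0 or 1. Natural logarithm throughout;
#' schemes calibrated on a log10 scale must say so in their config.
#'
#' @inheritParams compute_lnr
#' @return numeric vector on the natural-log-odds scale.
#' @export
compute_lodds <- function(pln, neln) {
  if (any(neln < 1)) stop("neln must be >= 1")
  if (any(pln < 0 | pln > neln)) stop("pln must satisfy 0 <= pln <= neln")
  log((pln + 0.5) / (neln - pln + 0.5))
}

#' AJCC/UICC 8th edition N category
#'
#' N0 when no node is positive (and no tumor deposits); N1 for 1-3
#' positive nodes, subdivided N1a (1) and N1b (2-3); N2 for 4 or more,
#' subdivided N2a (4-6) and N2b (>= 7). N1c marks tumor deposits without
#' positive regional nodes: category N1, subcategory N1c.
#'
#' @param pln positive lymph node count(s), `>= 0`.
#' @param n1c logical tumor-deposit flag(s).
#' @return data frame with character columns `n_cat` in
#'   `{"N0","N1","N2"}` and `n_subcat` in
#'   `{"none","N1a","N1b","N1c","N2a","N2b"}`.
#' @export
compute_n_category <- function(pln, n1c = FALSE) {
  n <- max(length(pln), length(n1c))
  pln <- rep_len(pln, n); n1c <- rep_len(as.logical(n1c), n)
  stopifnot(all(pln >= 0))
  if (any(n1c & pln > 0))
    stop("N1c is defined only for records with pln = 0")
  n_cat <- ifelse(pln == 0 & !n1c, "N0",
                  ifelse(pln <= 3, "N1", "N2"))
  n_subcat <- rep("none", n)
  n_subcat[n1c] <- "N1c"
  n_subcat[pln == 1] <- "N1a"
  n_subcat[pln %in% c(2, 3)] <- "N1b"
  n_subcat[pln >= 4 & pln <= 6] <- "N2a"
  n_subcat[pln >= 7] <- "N2b"
  n_cat[n1c] <- "N1"
  data.frame(n_cat = n_cat, n_subcat = n_subcat,
             stringsAsFactors = FALSE)
}

#' Append nodal staging metrics to a cohort
#'
#' Adds columns `lnr`, `lodds`, `n_cat`, `n_subcat` and `stage` (UICC
#' I/II/III via [derive_stage()]). An N1c record contributes `pln = 0` to
#' LNR/LODDS but is category N1 and stage III; the `n_subcat` column tags
#' it so reports can surface it separately.
#'
#' @param cohort a cohort.
#' @return the cohort with metric columns appended.
#' @export
add_nodal_metrics <- function(cohort) {
  cohort$lnr <- compute_lnr(cohort$pln, cohort$neln)
  cohort$lodds <- compute_lodds(cohort$pln, cohort$neln)
  nc <- compute_n_category(cohort$pln, cohort$n1c)
  cohort$n_cat <- nc$n_cat
  cohort$n_subcat <- nc$n_subcat
  cohort$stage <- derive_stage(cohort$t_cat, cohort$pln, cohort$n1c)
  cohort
}
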