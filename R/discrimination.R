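# Pairwise concordance bookkeeping shared by harrell_c() and the
# jackknife. For subjects i, j a pair is comparable when the shorter
# observed time belongs to a death (ties: two deaths at the same time are
# incomparable; a death tied with a censoring time counts, with the death
# as the failure). Returns symmetric n x n matrices of comparability
# (0/1) and concordance credit (0, 0.5, 1), each unordered pair appearing
# twice, so totals are halved and row sums give each subject's share —
# which is what makes leave-one-out C-statistics cheap.
.concordance_matrices <- function(scores, times, events) {
  n <- length(times)
  stopifnot(length(scores) == n, length(events) == n)
  lt <- outer(times, times, "<")
  eq <- outer(times, times, "==")
  e_row <- matrix(events == 1, n, n)            # event status of i
  e_col <- t(e_row)                             # event status of j
  # i is the failure of the pair:
  i_fail <- (lt & e_row) | (eq & e_row & !e_col)
  comparable <- i_fail | t(i_fail)
  diag(comparable) <- FALSE
  s_gt <- outer(scores, scores, ">")
  s_eq <- outer(scores, scores, "==")
  # a pair is concordant when its failure carries the strictly higher
  # score; tied scores earn 1/2; stored symmetrically
  conc <- i_fail & s_gt
  pair_credit <- matrix(0, n, n)
  pair_credit[conc | t(conc)] <- 1
  pair_credit[comparable & s_eq] <- 0.5
  list(comparable = comparable, credit = pair_credit)
}

#' Harrell's concordance index
#'
#' The probability, over comparable pairs under censoring, that the
#' subject with the higher risk score fails first. A pair is comparable
#' when the shorter observed time is a death; two deaths at the same time
#' are incomparable, and a death tied in time with a censored subject
#' counts with the death as the failure. Tied scores on a comparable pair
#' contribute 1/2. Higher score means shorter expected survival (the Cox
#' linear-predictor orientation).
#'
#' @param scores risk scores (higher = higher risk).
#' @param times positive follow-up times.
#' @param events death indicators in \{0,1\}.
#' @return list of class `concordance_result`: `c_index`, `n_pairs`
#'   (comparable pairs), `n_tied` (score-tied comparable pairs).
#' @export
harrell_c <- function(scores, times, events) {
  m <- .concordance_matrices(scores, times, events)
  n_pairs <- sum(m$comparable) / 2
  if (n_pairs == 0) stop("no comparable pairs")
  s_eq <- outer(scores, scores, "==")
  n_tied <- sum(m$comparable & s_eq) / 2
  structure(list(c_index = sum(m$credit) / 2 / n_pairs,
                 n_pairs = n_pairs, n_tied = n_tied),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f over %d comparable pairs (%g score-tied)\n",
              x$c_index, x$n_pairs, x$n_tied))
  invisible(x)
}

# leave-one-out C for every subject, from the pairwise matrices
.loo_c <- function(scores, times, events) {
  m <- .concordance_matrices(scores, times, events)
  tot_credit <- sum(m$credit) / 2
  tot_pairs <- sum(m$comparable) / 2
  if (tot_pairs == 0) stop("no comparable pairs")
  row_credit <- rowSums(m$credit)
  row_pairs <- rowSums(m$comparable)
  denom <- tot_pairs - row_pairs
  if (any(denom <= 0))
    stop("a leave-one-out sample has no comparable pairs")
  list(c = tot_credit / tot_pairs,
       loo = (tot_credit - row_credit) / denom)
}

#' Jackknife standard error of a single C-statistic
#'
#' Leave-one-out jackknife over subjects, the same machinery used for
#' paired differences; used to put a 95% CI on a reported C-index.
#'
#' @inheritParams harrell_c
#' @return list with `c_index`, `se`, `ci_low`, `ci_high`.
#' @export
jackknife_c_se <- function(scores, times, events) {
  n <- length(times)
  if (n < 3) stop("jackknife needs n >= 3")
  l <- .loo_c(scores, times, events)
  v <- (n - 1) / n * sum((l$loo - mean(l$loo))^2)
  se <- sqrt(v)
  z <- stats::qnorm(0.975)
  list(c_index = l$c, se = se,
       ci_low = l$c - z * se, ci_high = l$c + z * se)
}

#' Jackknife comparison of two C-statistics on the same subjects
#'
#' For risk models A and B evaluated on the same data, computes
#' Delta C = C_A - C_B together with its leave-one-out jackknife
#' standard error: for every subject the difference is recomputed on the
#' sample without that subject, and the jackknife variance is
#' ((n-1)/n) * sum over subjects of the squared deviation of those
#' leave-one-out differences from their mean. The 95% CI is
#' Delta C +/- 1.96 SE and the p-value is two-sided normal.
#'
#' @param scores_a risk scores of model A.
#' @param scores_b risk scores of model B (same subjects, same order).
#' @param times positive follow-up times.
#' @param events death indicators in \{0,1\}.
#' @return object of class `delta_c_result`: `delta_c`, `c_a`, `c_b`,
#'   `se`, `ci_low`, `ci_high`, `p_value`, `n`, and `note` ("identical"
#'   for a self-comparison, "degenerate" when SE is 0 with a non-zero
#'   difference).
#' @export
jackknife_delta_c <- function(scores_a, scores_b, times, events) {
  n <- length(times)
  if (n < 3) stop("jackknife needs n >= 3")
  stopifnot(length(scores_a) == n, length(scores_b) == n,
            length(events) == n)
  la <- .loo_c(scores_a, times, events)
  lb <- .loo_c(scores_b, times, events)
  delta <- la$c - lb$c
  d_loo <- la$loo - lb$loo
  v <- (n - 1) / n * sum((d_loo - mean(d_loo))^2)
  se <- sqrt(v)
  z <- stats::qnorm(0.975)
  note <- NULL
  if (identical(scores_a, scores_b)) note <- "identical"
  else if (se == 0 && delta != 0) note <- "degenerate"
  p <- if (se == 0) {
    if (delta == 0) NA_real_ else 0
  } else 2 * stats::pnorm(-abs(delta / se))
  structure(list(delta_c = delta, c_a = la$c, c_b = lb$c, se = se,
                 ci_low = delta - z * se, ci_high = delta + z * se,
                 p_value = p, n = n, note = note),
            class = "delta_c_result")
}

#' @export
print.delta_c_result <- function(x, ...) {
  cat(sprintf(
    "Delta C = %.4f (C_A %.4f vs C_B %.4f), jackknife SE %.4f,\n  95%% CI [%.4f, %.4f], p = %s%s\n",
    x$delta_c, x$c_a, x$c_b, x$se, x$ci_low, x$ci_high,
    format.pval(x$p_value, digits = 3),
    if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, the k-th adjusted
#' value is the minimum over j >= k of p_(j) * m / j, capped at 1, and
#' results are returned in the input order. `m` defaults to the number of
#' p-values but can be set larger when the comparison family is wider
#' than the vector supplied.
#'
#' @param p p-values in \[0, 1\].
#' @param m family size (default `length(p)`).
#' @return adjusted p-values, input order.
#' @export
fdr_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= length(p))
  n <- length(p)
  if (n == 0) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Landmark ROC AUC for censored survival
#'
#' Discrimination of a risk score for death by a fixed horizon: cases are
#' subjects who died at or before the horizon, controls are subjects
#' followed beyond it, and subjects censored at or before the horizon are
#' excluded. The AUC is the Mann-Whitney probability that a random case
#' scores above a random control, with tied scores counting 1/2. (No
#' censoring reweighting — excluded subjects are a documented limitation.)
#'
#' @param scores risk scores (higher = higher risk of death).
#' @param times positive follow-up times (months).
#' @param events death indicators in \{0,1\}.
#' @param horizon landmark time in months (> 0).
#' @return object of class `landmark_auc`: `horizon`, `auc`, `n_cases`,
#'   `n_controls`, `n_excluded`.
#' @export
landmark_auc <- function(scores, times, events, horizon) {
  stopifnot(horizon > 0, length(scores) == length(times),
            length(times) == length(events))
  case <- times <= horizon & events == 1
  control <- times > horizon
  excluded <- !case & !control
  if (!any(case)) stop("no cases (deaths) at or before the horizon")
  if (!any(control)) stop("no controls followed beyond the horizon")
  sc <- scores[case]; sk <- scores[control]
  # Mann-Whitney U via midranks over the pooled scores
  r <- rank(c(sc, sk), ties.method = "average")
  u <- sum(r[seq_along(sc)]) - length(sc) * (length(sc) + 1) / 2
  structure(list(horizon = horizon,
                 auc = u / (length(sc) * length(sk)),
                 n_cases = length(sc), n_controls = length(sk),
                 n_excluded = sum(excluded)),
            class = "landmark_auc")
}

#' @export
print.landmark_auc <- function(x, ...) {
  cat(sprintf(
    "landmark AUC at %g months: %.4f (%d cases, %d controls, %d excluded)\n",
    x$horizon, x$auc, x$n_cases, x$n_controls, x$n_excluded))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("spearman correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
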