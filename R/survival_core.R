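#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times (months).
#' @param events death indicators in \{0,1\}.
#' @return object of class `km_curve`: event times, survival
#'   probabilities, at-risk counts, event and censoring counts.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "distinct times,",
      sum(x$n_event), "events\n")
  invisible(x)
}

#' Log-rank (Mantel-Cox) test
#'
#' Observed-versus-expected chi-square over the pooled event times.
#'
#' @param times positive follow-up times.
#' @param events death indicators in \{0,1\}.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list of class `logrank_result`: `chisq`, `df`
#'   (groups - 1), `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("log-rank test needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  structure(list(chisq = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square %.4f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with the Efron
#' approximation for tied event times (Breslow available), convergence at
#' relative log-likelihood change below 1e-9 or 50 iterations. Wald 95%
#' CIs on the hazard-ratio scale. Constant (including all-zero) columns
#' are dropped with a warning — the empty-class case when classification
#' indicators enter the model. Suspected monotone likelihood (complete
#' separation) is flagged, not silently returned.
#'
#' @param x numeric design matrix (or data frame), one column per
#'   covariate; class indicators should contrast against the reference
#'   class.
#' @param times positive follow-up times.
#' @param events death indicators in \{0,1\} (>= 1 event).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit` with `coefficients`, `var`
#'   (covariance), `hr` table (HR, CI bounds, z, p per term), `loglik`
#'   (null, final), `iter`, `converged`, `flagged` (separation or
#'   non-convergence message or `NULL`), `dropped` columns,
#'   `linear_predictor` (x %*% beta, dropped columns excluded), `n`,
#'   `n_event`.
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("no events")
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  dropped <- colnames(x)[const]
  if (length(dropped) > 0) {
    warning("dropping constant column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) == 0) {
    # null model: no estimable effect
    null_ll <- survival::coxph(
      survival::Surv(times, events) ~ 1, ties = ties)$loglik
    return(structure(list(
      coefficients = stats::setNames(numeric(0), character(0)),
      var = matrix(0, 0, 0), hr = NULL, loglik = c(null_ll, null_ll),
      iter = 0L, converged = TRUE, flagged = NULL, dropped = dropped,
      linear_predictor = rep(0, length(times)), n = length(times),
      n_event = sum(events)), class = "cox_fit"))
  }
  flagged <- NULL
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  names(beta) <- colnames(x)  # coxph mangles matrix-term names
  se <- sqrt(diag(as.matrix(fit$var)))
  if (anyNA(beta) || any(abs(beta) > 15))
    flagged <- c(flagged, "coefficient magnitude suggests monotone likelihood")
  converged <- is.null(fit$info) && !anyNA(beta) &&
    !any(grepl("did not converge|infinite|out of iterations|singular",
               paste(flagged, collapse = " "), ignore.case = TRUE))
  z <- stats::qnorm(0.975)
  hr <- data.frame(term = names(beta), coef = unname(beta),
                   se = unname(se), hr = exp(unname(beta)),
                   ci_low = exp(unname(beta) - z * unname(se)),
                   ci_high = exp(unname(beta) + z * unname(se)),
                   p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                   stringsAsFactors = FALSE)
  vcov <- as.matrix(fit$var)
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, var = vcov, hr = hr,
                 loglik = fit$loglik, iter = fit$iter,
                 converged = converged, flagged = flagged,
                 dropped = dropped,
                 linear_predictor = as.vector(x %*% beta),
                 n = length(times), n_event = sum(events)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox PH fit:", x$n, "subjects,", x$n_event, "events;",
      x$iter, "iterations", if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$hr)) {
    tab <- x$hr
    tab$`HR (95% CI)` <- sprintf("%.*f (%.*f-%.*f)", digits, tab$hr,
                                 digits, tab$ci_low, digits, tab$ci_high)
    print(tab[, c("term", "HR (95% CI)", "p")], row.names = FALSE)
  }
  if (!is.null(x$flagged))
    cat("flags:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Encode the base-model covariates
#'
#' Dichotomised exactly as in the adjusted base model: age >= 70, male
#' sex, tumour size at or above the analysis-cohort median, poor
#' differentiation (G3 + G4; `unknown` counts with the G1 + G2 reference
#' after imputation), advanced T (T3 + T4), and rectal location. The size
#' median is computed on the cohort passed in — pass `size_median` to
#' reuse a median computed elsewhere (e.g. the full cohort's, when
#' encoding a subgroup the same way).
#'
#' @param cohort a cohort (imputed: no missing covariates).
#' @param size_median optional fixed cut for the size indicator.
#' @return numeric 0/1 matrix with columns `age_ge70, male,
#'   size_ge_median, grade_g34, t_34, rectum`; the cut used is attached
#'   as attribute `"size_median"`.
#' @export
encode_covariates <- function(cohort, size_median = NULL) {
  if (is.null(size_median)) size_median <- stats::median(cohort$size_mm)
  m <- cbind(
    age_ge70 = as.numeric(cohort$age >= 70),
    male = as.numeric(cohort$sex == "male"),
    size_ge_median = as.numeric(cohort$size_mm >= size_median),
    grade_g34 = as.numeric(cohort$grade %in% c("G3", "G4")),
    t_34 = as.numeric(cohort$t_cat %in% c("T3", "T4")),
    rectum = as.numeric(cohort$location == "rectum"))
  if (anyNA(m)) stop("missing covariate values; run impute_missing() first")
  attr(m, "size_median") <- size_median
  m
}

#' Fit the adjusted base model
#'
#' The six-covariate Cox model used to adjust every nodal-classification
#' comparison: age >= 70, male sex, tumour size >= median, G3+G4, T3+T4,
#' rectal location. Additional columns (e.g. a continuous LODDS term or
#' classification-class indicators) can be appended via `extra`.
#'
#' @param cohort an imputed cohort.
#' @param extra optional named numeric matrix/data frame of additional
#'   model columns, or character vector naming cohort columns to append.
#' @param size_median optional fixed size cut (see [encode_covariates()]).
#' @param ties tie handling, `"efron"` default.
#' @return a [cox_fit()] object; the encoding's size cut is attached as
#'   attribute `"size_median"`.
#' @export
fit_base_model <- function(cohort, extra = NULL, size_median = NULL,
                           ties = "efron") {
  x <- encode_covariates(cohort, size_median = size_median)
  if (!is.null(extra)) {
    if (is.character(extra)) {
      stopifnot(all(extra %in% names(cohort)))
      extra <- as.matrix(as.data.frame(cohort)[, extra, drop = FALSE])
    }
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(x))
    x <- cbind(x, extra)
  }
  fit <- cox_fit(x, cohort$time_months, cohort$event, ties = ties)
  attr(fit, "size_median") <- attr(x, "size_median")
  fit
}

#' Events required for a two-group log-rank test
#'
#' Schoenfeld's formula: the number of events required for a two-sided
#' level-`alpha` log-rank test to reach the given power against a
#' constant hazard ratio `hr`, with an `allocation` fraction in one arm:
#' D = (z_(1-alpha/2) + z_power)^2 / (p (1 - p) (ln hr)^2), rounded up.
#' Total sample size is D divided by the anticipated event fraction.
#'
#' @param hr hazard ratio under the alternative (not 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param allocation fraction of subjects in the first arm.
#' @param event_fraction anticipated overall event fraction (optional).
#' @return list with `events` (integer) and, when `event_fraction` is
#'   given, `total_n`.
#' @export
logrank_power <- function(hr, alpha = 0.05, power = 0.90,
                          allocation = 0.5, event_fraction = NULL) {
  if (hr == 1) stop("hr must differ from 1")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            allocation > 0, allocation < 1)
  d <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
    (allocation * (1 - allocation) * log(hr)^2)
  out <- list(events = as.integer(ceiling(d)))
  if (!is.null(event_fraction))
    out$total_n <- as.integer(ceiling(out$events / event_fraction))
  out
}
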