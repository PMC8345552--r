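# Independent brute-force oracles and small fixture builders. The
# oracles are written as plain loops over pairs/deletions, sharing no
# code with the package's vectorised implementations.

# minimal well-formed cohort rows for IO / filtering tests
make_cohort_df <- function(n, time = NULL, event = NULL, pln = NULL,
                           neln = NULL, t_cat = "T3") {
  data.frame(
    id = sprintf("S%03d", seq_len(n)),
    time_months = time %||% seq_len(n) + 0.5,
    event = event %||% rep(1L, n),
    age = rep(65, n), sex = rep("male", n),
    neln = neln %||% rep(15L, n), pln = pln %||% rep(0L, n),
    t_cat = rep(t_cat, length.out = n), grade = rep("G2", n),
    size_mm = rep(40, n), location = rep("sigmoid", n),
    neoadjuvant = rep("no", n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harrell concordance by exhaustive pair enumeration. Comparability:
# strictly shorter time with an event, or equal times with exactly one
# event (the event is the failure); two events at the same time are
# incomparable. Credit: failure has higher score -> 1, tie -> 0.5.
bf_concordance <- function(scores, times, events) {
  n <- length(times)
  num <- 0; den <- 0; tied <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fail <- NA
    if (times[i] < times[j] && events[i] == 1) fail <- i
    else if (times[j] < times[i] && events[j] == 1) fail <- j
    else if (times[i] == times[j] && events[i] + events[j] == 1)
      fail <- if (events[i] == 1) i else j
    if (is.na(fail)) next
    other <- if (fail == i) j else i
    den <- den + 1
    if (scores[fail] > scores[other]) num <- num + 1
    else if (scores[fail] == scores[other]) { num <- num + 0.5;
      tied <- tied + 1 }
  }
  list(c = num / den, n_pairs = den, n_tied = tied)
}

# naive jackknife of Delta C: full recomputation of both C-statistics on
# every leave-one-out sample
bf_jackknife_delta_c <- function(sa, sb, times, events) {
  n <- length(times)
  d_full <- bf_concordance(sa, times, events)$c -
    bf_concordance(sb, times, events)$c
  d_loo <- vapply(seq_len(n), function(i) {
    bf_concordance(sa[-i], times[-i], events[-i])$c -
      bf_concordance(sb[-i], times[-i], events[-i])$c
  }, numeric(1))
  v <- (n - 1) / n * sum((d_loo - mean(d_loo))^2)
  list(delta = d_full, se = sqrt(v))
}

# random censored survival data guaranteed to have comparable pairs in
# every leave-one-out sample (at least three distinct event times)
random_surv_data <- function(n, tie_free = TRUE, score_ties = FALSE) {
  repeat {
    times <- if (tie_free) round(runif(n, 1, 100), 3) else
      sample(1:8, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    scores <- if (score_ties) sample(1:3, n, replace = TRUE) else
      round(rnorm(n), 3)
    if (sum(events) >= 3 && length(unique(times[events == 1])) >= 3 &&
        (!tie_free || !anyDuplicated(times)))
      return(list(times = times, events = events, scores = scores))
  }
}

# 1-D Cox partial log-likelihood for a single covariate (Breslow ties),
# evaluated directly from the risk-set definition
bf_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
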