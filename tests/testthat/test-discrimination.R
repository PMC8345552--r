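test_that("Harrell's C on hand-checkable configurations", {
  # perfect ranking: higher score dies earlier
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))$c_index, 1)
  # worked mixed-censoring case: (1,2) concordant, (1,3) discordant,
  # (2,3) incomparable -> C = 0.5
  r <- harrell_c(c(2, 1, 3), c(1, 2, 3), c(1, 0, 1))
  expect_equal(r$c_index, 0.5)
  expect_equal(r$n_pairs, 2)
  # complete score ties: C = 0.5 with every comparable pair tied
  r2 <- harrell_c(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(r2$c_index, 0.5)
  expect_equal(r2$n_tied, 3)
  expect_error(harrell_c(1, 5, 0), "comparable")
})

test_that("Harrell's C equals exhaustive pair enumeration on random cohorts", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    d <- random_surv_data(n, tie_free = i %% 2 == 0,
                          score_ties = i %% 3 == 0)
    got <- harrell_c(d$scores, d$times, d$events)
    want <- bf_concordance(d$scores, d$times, d$events)
    expect_equal(got$c_index, want$c, tolerance = 1e-14)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("C is invariant to monotone score transforms; complement flips it", {
  set.seed(55)
  d <- random_surv_data(30)
  c1 <- harrell_c(d$scores, d$times, d$events)$c_index
  expect_equal(harrell_c(exp(2 * d$scores), d$times, d$events)$c_index, c1)
  expect_equal(harrell_c(rank(d$scores), d$times, d$events)$c_index, c1)
  # no score ties: reversing scores complements C
  expect_equal(harrell_c(-d$scores, d$times, d$events)$c_index, 1 - c1)
})

test_that("jackknife Delta C matches the naive full-recompute oracle", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    d <- random_surv_data(n, tie_free = i %% 2 == 0)
    sb <- round(rnorm(n), 3)
    got <- tryCatch(jackknife_delta_c(d$scores, sb, d$times, d$events),
                    error = function(e) e)
    if (inherits(got, "error")) {
      expect_match(conditionMessage(got), "comparable|leave-one-out")
      next
    }
    want <- bf_jackknife_delta_c(d$scores, sb, d$times, d$events)
    expect_equal(got$delta_c, want$delta, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
  }
})

test_that("Delta C: self-comparison, antisymmetry, CI construction", {
  set.seed(7)
  d <- random_surv_data(20)
  sb <- rnorm(20)
  self <- jackknife_delta_c(d$scores, d$scores, d$times, d$events)
  expect_equal(self$delta_c, 0)
  expect_equal(self$se, 0)
  expect_equal(self$note, "identical")
  ab <- jackknife_delta_c(d$scores, sb, d$times, d$events)
  ba <- jackknife_delta_c(sb, d$scores, d$times, d$events)
  expect_equal(ab$delta_c, -ba$delta_c)
  expect_equal(ab$se, ba$se)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$ci_low, ab$delta_c - qnorm(0.975) * ab$se)
  expect_equal(ab$ci_high, ab$delta_c + qnorm(0.975) * ab$se)
  expect_error(jackknife_delta_c(1:2, 2:1, c(1, 2), c(1, 1)), "n >= 3")
  # single-C jackknife CI brackets the point estimate
  cse <- jackknife_c_se(d$scores, d$times, d$events)
  expect_true(cse$ci_low <= cse$c_index && cse$c_index <= cse$ci_high)
})

test_that("BH step-up adjustment: hand example, properties, stats oracle", {
  expect_equal(fdr_adjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
  # family wider than the supplied vector
  expect_equal(fdr_adjust(c(0.01, 0.02), m = 4), c(0.04, 0.04))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p - 1e-15))
    # monotone: ordering preserved
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("landmark AUC: separation, U-statistic oracle, exclusions", {
  # perfect separation
  a <- landmark_auc(c(9, 8, 1, 2), c(3, 5, 40, 50), c(1, 1, 0, 0), 12)
  expect_equal(a$auc, 1)
  expect_equal(a$n_cases, 2); expect_equal(a$n_controls, 2)
  # constructed tie set: identical scores -> exactly 0.5
  expect_equal(landmark_auc(rep(1, 6), c(1, 2, 3, 20, 30, 40),
                            c(1, 1, 1, 0, 0, 0), 12)$auc, 0.5)
  # 3 cases / 3 controls, one crossing pair -> 8/9
  sc <- c(10, 9, 5, 6, 2, 1)
  tm <- c(1, 2, 3, 90, 91, 92); ev <- c(1, 1, 1, 0, 0, 0)
  expect_equal(landmark_auc(sc, tm, ev, 12)$auc, 8 / 9)
  # censored before the horizon excluded; errors without cases/controls
  b <- landmark_auc(c(5, 4, 3, 2), c(3, 6, 50, 60), c(1, 0, 0, 0), 12)
  expect_equal(b$n_excluded, 1)
  expect_error(landmark_auc(1:3, c(20, 30, 40), c(0, 0, 0), 12), "cases")
  expect_error(landmark_auc(1:3, c(1, 2, 3), c(1, 1, 1), 12), "controls")
})

test_that("without censoring, landmark AUC equals C on the dichotomised outcome", {
  set.seed(88)
  n <- 40
  scores <- rnorm(n)
  times <- runif(n, 1, 100)
  events <- rep(1, n)  # no censoring
  h <- 50
  a <- landmark_auc(scores, times, events, h)$auc
  # dichotomised data: died by h (time 1) vs survived (time 2), all events
  bin_t <- ifelse(times <= h, 1, 2)
  cc <- bf_concordance(scores, bin_t, rep(1, n))
  expect_equal(a, cc$c)
})

test_that("Spearman rank correlation with midranks", {
  expect_equal(spearman_rho(1:5, (1:5)^3), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman_rho(x, y),
               unname(cor(x, y, method = "spearman")))
  # ties handled by midranks, still matching the reference
  xt <- sample(1:5, 30, replace = TRUE)
  yt <- sample(1:4, 30, replace = TRUE)
  expect_equal(spearman_rho(xt, yt),
               unname(cor(xt, yt, method = "spearman")))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})
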