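test_that("Kaplan-Meier matches hand product-limit computations", {
  # no censoring: empirical survival
  km <- km_estimate(c(2, 3, 7), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censored subject leaves the risk set after its time
  km2 <- km_estimate(c(2, 3, 5, 7), c(1, 1, 0, 1))
  expect_equal(km2$surv[km2$time == 3], 0.75 * (2 / 3))
  expect_equal(km2$surv[km2$time == 7], 0)
  # all censored: survival stays at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  # non-increasing, starts at/below 1
  set.seed(5)
  d <- random_surv_data(40)
  km4 <- km_estimate(d$times, d$events)
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_true(all(km4$surv <= 1))
})

test_that("log-rank test: symmetry zero, hand computation, df", {
  # duplicated groups: statistic 0
  t0 <- c(1, 3, 5, 8); e0 <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 4 subjects, one event per group, non-overlapping times:
  # hand hypergeometric sums over the two event times
  # subjects: A(t=1,event), A(t=4,cens), B(t=2,event), B(t=3,cens)
  tt <- c(1, 4, 2, 3); ee <- c(1, 0, 1, 0); gg <- c("A", "A", "B", "B")
  # time 1: n=4, nA=2, O_A=1, E_A=0.5, V=0.25 (one event)
  # time 2: n=3, nA=1, O_A=0, E_A=1/3, V=2/9
  # U = (1-0.5) + (0-1/3) = 1/6; Var = 1/4 + 2/9 = 17/36
  expect_equal(logrank_test(tt, ee, gg)$chisq, (1 / 6)^2 / (17 / 36),
               tolerance = 1e-10)
  expect_equal(logrank_test(tt, ee, gg)$df, 1)

  set.seed(9)
  d <- random_surv_data(30)
  g3 <- rep(c("x", "y", "z"), 10)
  expect_equal(logrank_test(d$times, d$events, g3)$df, 2)
  expect_error(logrank_test(d$times, d$events, rep("x", 30)), "2 groups")
})

test_that("single-covariate Cox fits maximise the hand-written partial likelihood", {
  # the 4-subject textbook case: PL(a) = a/(2a+2) * 1/(a+2) * a/(a+1)
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 0); xx <- c(1, 0, 1, 0)
  fit <- cox_fit(cbind(z = xx), tt, ee)
  pl <- function(b) {
    a <- exp(b)
    log(a / (2 * a + 2)) + log(1 / (a + 2)) + log(a / (a + 1))
  }
  opt <- optimize(pl, c(-5, 5), maximum = TRUE)
  expect_equal(unname(fit$coefficients["z"]), opt$maximum,
               tolerance = 1e-5)
  expect_equal(fit$loglik[2], opt$objective, tolerance = 1e-8)

  # 100 random tiny cohorts against brute-force 1-D maximisation
  set.seed(31)
  for (rep_i in 1:100) {
    n <- sample(6:12, 1)
    d <- random_surv_data(n)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) next
    f <- cox_fit(cbind(x = x), d$times, d$events, ties = "breslow")
    if (!f$converged || !is.null(f$flagged)) next  # separation on tiny data
    o <- optimize(function(b) bf_cox_loglik(b, x, d$times, d$events),
                  c(-20, 20), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(unname(f$coefficients["x"]) - o$maximum), 1e-6)
  }
})

test_that("Cox contracts: no events, constant column, permutation invariance", {
  tt <- c(1, 2, 3, 4); xx <- c(1, 0, 1, 0)
  expect_error(cox_fit(cbind(x = xx), tt, c(0, 0, 0, 0)), "no events")
  # identically zero covariate: dropped, loglik equals null model
  expect_warning(f0 <- cox_fit(cbind(x = rep(0, 4)), tt, c(1, 1, 1, 0)),
                 "constant")
  expect_length(f0$coefficients, 0)
  expect_equal(f0$loglik[1], f0$loglik[2])
  # row permutation leaves estimates unchanged
  set.seed(12)
  d <- random_surv_data(50)
  x <- cbind(a = rbinom(50, 1, 0.4), b = rnorm(50))
  f1 <- cox_fit(x, d$times, d$events)
  p <- sample(50)
  f2 <- cox_fit(x[p, ], d$times[p], d$events[p])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$var, f2$var, tolerance = 1e-10)
  # CI bounds bracket the HR
  expect_true(all(f1$hr$ci_low <= f1$hr$hr & f1$hr$hr <= f1$hr$ci_high))
})

test_that("duplicating every row halves the variance (SE shrinks by sqrt 2)", {
  set.seed(77)
  d <- random_surv_data(60)
  x <- cbind(z = rbinom(60, 1, 0.5))
  f1 <- cox_fit(x, d$times, d$events, ties = "breslow")
  f2 <- cox_fit(rbind(x, x), c(d$times, d$times), c(d$events, d$events),
                ties = "breslow")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$hr$se / sqrt(2), f2$hr$se, tolerance = 1e-6)
})

test_that("two-group log-rank equals the Cox score test at beta = 0", {
  set.seed(21)
  for (i in 1:5) {
    d <- random_surv_data(40)
    g <- rbinom(40, 1, 0.5)
    if (length(unique(g)) < 2) g[1] <- 1 - g[1]
    lr <- logrank_test(d$times, d$events, g)
    sc <- survival::coxph(survival::Surv(d$times, d$events) ~ g)
    expect_equal(lr$chisq, unname(sc$score), tolerance = 1e-8)
  }
})

test_that("base model recovers generating coefficients when fit matches truth", {
  # moderate-n sanity version of the n = 20000 acceptance check:
  # fit the generating model (base + continuous LODDS) and compare
  cfg <- sim_config(seed = 100, n = 6000)
  co <- impute_missing(add_nodal_metrics(simulate_cohort(cfg)))
  fit <- fit_base_model(co, extra = "lodds",
                        size_median = attr(co, "sim_truth")$size_median)
  truth <- c(cfg$coefficients, lodds = unname(cfg$node_effect["lodds"]))
  est <- fit$coefficients[names(truth)]
  # 6000 subjects: looser net than the acceptance tolerance
  expect_true(all(abs(est - truth) < 3.5 * fit$hr$se[match(names(truth),
                                                           fit$hr$term)]))
  expect_true(fit$converged)
  expect_error(fit_base_model(co[co$event == 0, ][1:10, ]), "no events")
})

test_that("Schoenfeld events formula and its monotonicity", {
  expect_equal(logrank_power(1.5, 0.05, 0.90, 0.5)$events, 256L)
  expect_equal(logrank_power(2.0, 0.05, 0.90, 0.5)$events, 88L)
  expect_equal(logrank_power(1.5, 0.05, 0.90, 0.5,
                             event_fraction = 0.5)$total_n, 512L)
  # required events decrease as alpha grows
  d_alpha <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a)
    (qnorm(1 - a / 2) + qnorm(0.9))^2 / (0.25 * log(1.5)^2), numeric(1))
  expect_true(all(diff(d_alpha) < 0))
  expect_error(logrank_power(1), "differ from 1")
})
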