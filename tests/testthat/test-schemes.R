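test_that("built-in schemes carry the published boundaries", {
  s <- builtin_schemes()
  expect_length(s, 8)
  lee <- s[["LNR Lee"]]
  expect_equal(nrow(lee$classes), 4)
  expect_equal(lee$classes$upper[1:3], c(0.1, 0.2, 0.3))
  he <- s[["LODDS He"]]
  expect_equal(nrow(he$classes), 5)
  expect_equal(he$classes$upper[1:4], c(-3, -2, -1, 0))
  jh <- s[["LODDS Jian-Hui"]]
  expect_equal(nrow(jh$classes), 4)
  expect_equal(jh$classes$upper[1:3], c(-1.5, -1, 0))
  # repaired schemes say so
  expect_match(s[["LNR Fortea-Sanchis"]]$repairs, "0.25")
  expect_match(s[["LODDS Bagante"]]$repairs, "sign slip")
  for (sc in s) if (sc$kind == "fixed") expect_true(validate_scheme(sc))
})

test_that("classification respects printed bound symbols at the boundaries", {
  s <- builtin_schemes()
  lee <- s[["LNR Lee"]]
  expect_equal(as.integer(classify(0.10, lee)), 1)  # <=0.1 closes class 1
  expect_equal(as.integer(classify(c(0.30, 0.301), lee)), c(3, 4))
  jh <- s[["LODDS Jian-Hui"]]
  expect_equal(as.integer(classify(c(0, 0.001), jh)), c(3, 4))
  bag <- s[["LODDS Bagante"]]
  expect_equal(as.integer(classify(c(-2, -0.9, -0.89, 1.5, 1.51), bag)),
               c(2, 2, 3, 3, 4))
  cal <- s[["LODDS Calero"]]
  expect_equal(as.integer(classify(c(-3, -2.999, 3, 3.001), cal)),
               c(1, 2, 3, 4))
  expect_error(classify(0.5, s[["LODDS quantile"]]), "unfitted")
})

test_that("every shipped scheme classifies the whole attainable node grid, monotonically", {
  grid <- expand.grid(n = 1:100, p = 0:100)
  grid <- grid[grid$p <= grid$n, ]
  lnr <- compute_lnr(grid$p, grid$n)
  lodds <- compute_lodds(grid$p, grid$n)
  for (s in builtin_schemes()) {
    if (s$kind == "quantile") next
    v <- if (s$variable == "LNR") lnr else lodds
    idx <- classify(v, s)  # errors if any value is unassigned
    expect_true(all(idx >= 1 & idx <= nrow(s$classes)))
    # class index monotone non-decreasing in pln at fixed neln
    for (n in c(1, 12, 45, 100)) {
      sel <- grid$n == n
      expect_true(all(diff(idx[sel][order(grid$p[sel])]) >= 0),
                  label = paste(s$name, "monotone at neln", n))
    }
  }
})

test_that("classify agrees with a brute-force linear scan on random values", {
  set.seed(42)
  for (s in builtin_schemes()) {
    if (s$kind == "quantile") next
    v <- if (s$variable == "LNR") runif(20000) else runif(20000, -6, 6)
    # include exact boundary points
    v <- c(v, s$classes$lower[is.finite(s$classes$lower)],
           s$classes$upper[is.finite(s$classes$upper)])
    got <- as.integer(classify(v, s))
    cl <- s$classes
    want <- vapply(v, function(x) {
      for (k in seq_len(nrow(cl))) {
        lo_ok <- x > cl$lower[k] || (cl$lower_closed[k] && x == cl$lower[k])
        hi_ok <- x < cl$upper[k] || (cl$upper_closed[k] && x == cl$upper[k])
        if (lo_ok && hi_ok) return(k)
      }
      NA_integer_
    }, integer(1))
    expect_equal(got, want, label = s$name)
  }
})

test_that("quantile scheme uses interpolated percentiles and handles extremes", {
  s <- fit_quantile_scheme(c(1, 2, 3, 4))
  expect_equal(s$cut_points, c(1.75, 2.5, 3.25))
  expect_equal(as.integer(classify(1, s)), 1)
  expect_equal(as.integer(classify(4, s)), 4)
  expect_equal(as.integer(classify(c(1.75, 2.5), s)), c(2, 3))
  expect_error(fit_quantile_scheme(rep(2, 10)), "distinct")
  expect_error(fit_quantile_scheme(c(1, 2)), "distinct")
  # degenerate cuts from heavy duplication (4 distinct values, tied quantiles)
  expect_error(fit_quantile_scheme(c(1, 2, rep(5, 20), 9)),
               "non-distinct quantiles")
})

test_that("JSON scheme config round-trips and is validated", {
  s <- builtin_schemes()
  path <- withr::local_tempfile(fileext = ".json")
  write_schemes(s[c("LNR Lee", "LODDS He")], path)
  back <- load_schemes(path)
  expect_equal(back[["LNR Lee"]]$classes, s[["LNR Lee"]]$classes)
  expect_equal(back[["LODDS He"]]$classes, s[["LODDS He"]]$classes)
  expect_equal(as.integer(classify(c(0.1, 0.25, 0.9),
                                   back[["LNR Lee"]])),
               as.integer(classify(c(0.1, 0.25, 0.9), s[["LNR Lee"]])))

  # overlapping classes rejected, citing the pair
  bad <- list(list(name = "bad", variable = "LNR", classes = list(
    list(label = "a", lower = 0, lower_closed = TRUE,
         upper = 0.2, upper_closed = TRUE),
    list(label = "b", lower = 0.1, lower_closed = TRUE,
         upper = 1, upper_closed = TRUE))))
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_schemes(path), "overlap")

  # gap accepted only under an explicit repair directive
  gap <- list(list(name = "gappy", variable = "LNR", classes = list(
    list(label = "a", lower = 0, lower_closed = TRUE,
         upper = 0.24, upper_closed = TRUE),
    list(label = "b", lower = 0.3, lower_closed = TRUE,
         upper = 1, upper_closed = TRUE))))
  jsonlite::write_json(gap, path, auto_unbox = TRUE)
  expect_error(load_schemes(path), "gap")
  gap[[1]]$repair <- "extend_left"
  jsonlite::write_json(gap, path, auto_unbox = TRUE)
  rep <- load_schemes(path)[["gappy"]]
  expect_true(validate_scheme(rep))
  expect_match(rep$repairs, "extend_left")
  expect_equal(as.integer(classify(0.27, rep)), 2)  # gap now covered
})
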