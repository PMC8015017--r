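# Frozen expected values for the (7,13,29,151) table were computed from the
# closed-form definitions with an independent standalone evaluation.

test_that("ROR point estimate and Woolf interval are exact", {
  sym <- compute_ror(c(1, 1, 1, 1))
  expect_equal(sym$ror, 1)
  expect_equal(sym$ci_low, exp(-1.96 * 2))
  expect_equal(sym$ci_high, exp(1.96 * 2))
  expect_false(sym$signal)

  r <- compute_ror(c(7, 13, 29, 151))
  expect_equal(r$ror, 2.803714, tolerance = 1e-6)
  expect_equal(r$ci_low, 1.030286, tolerance = 1e-6)
  expect_equal(r$ci_high, 7.629734, tolerance = 1e-6)
  expect_true(r$signal)

  # cross-product identity whenever defined
  for (cells in list(c(3, 9, 2, 40), c(12, 1383, 1503, 700948), c(5, 5, 7, 2))) {
    rr <- compute_ror(cells)
    expect_equal(rr$ror * cells[2] * cells[3], cells[1] * cells[4],
                 tolerance = 1e-9)
  }

  zero <- compute_ror(c(0, 10, 5, 100))
  expect_false(zero$defined)
  expect_true(is.na(zero$ror))
  expect_false(zero$signal)
  haldane <- compute_ror(c(0, 10, 5, 100), haldane = TRUE)
  expect_true(haldane$defined)
  expect_equal(haldane$ror, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("PRR and the Yates chi-square follow the corrected formulas", {
  sym <- compute_prr(c(1, 1, 1, 1))
  expect_equal(sym$prr, 1)
  expect_equal(sym$chi2, 0)  # |O - E| = 0 in every cell, correction floored
  expect_false(sym$signal)

  p <- compute_prr(c(7, 13, 29, 151))
  expect_equal(p$prr, 2.172414, tolerance = 1e-6)
  expect_equal(p$chi2, 3.165462, tolerance = 1e-6)
  expect_equal(p$n, 7)
  expect_false(p$signal)  # chi-square below 4

  # three-part criterion: each leg alone can block the signal
  strong <- compute_prr(c(30, 70, 100, 9800))
  expect_true(strong$signal)
  small_n <- compute_prr(c(2, 3, 100, 9895))
  expect_false(small_n$signal)  # n < 3

  undef <- compute_prr(c(0, 0, 5, 95))
  expect_false(undef$defined)
  expect_false(undef$signal)
  no_event_background <- compute_prr(c(3, 7, 0, 90))
  expect_false(no_event_background$defined)
})

test_that("IC expectation and variance match the shrinkage formulas", {
  sym <- compute_ic(c(1, 1, 1, 1))
  expect_identical(sym$ic, 0)  # gamma = 36/9; numerator and denominator equal
  expect_false(sym$signal)

  i <- compute_ic(c(7, 13, 29, 151))
  expect_equal(i$ic, 0.7344280, tolerance = 1e-6)
  expect_equal(i$variance, 0.3850294, tolerance = 1e-6)
  expect_equal(i$ci_low, -0.4817664, tolerance = 1e-5)
  expect_equal(i$ci_high, 1.9506225, tolerance = 1e-5)
  expect_false(i$signal)

  # defined on zero cells, shrunk toward 0
  z <- compute_ic(c(0, 20, 30, 950))
  expect_true(is.finite(z$ic))

  # monotone in a for fixed margins and total
  cx <- 40; cy <- 60; N <- 1000
  ics <- vapply(0:30, function(a) {
    compute_ic(c(a, cx - a, cy - a, N - cx - cy + a))$ic
  }, 0)
  expect_true(all(diff(ics) > 0))
})

test_that("IC approaches the raw log2 observed-over-expected as counts grow", {
  base <- c(6, 14, 24, 156)
  raw <- function(x) {
    N <- sum(x)
    log2(x[1] * N / ((x[1] + x[2]) * (x[1] + x[3])))
  }
  errs <- vapply(c(10, 100, 1000), function(k) {
    abs(compute_ic(base * k)$ic - raw(base * k))
  }, 0)
  expect_true(all(diff(errs) < 0))  # shrinkage vanishes as counts grow
  expect_lt(errs[3], 0.001)
})

test_that("delta and Monte Carlo IC intervals agree on large tables", {
  tab <- c(120, 380, 480, 9020)  # all cells >= 100
  delta <- compute_ic(tab, ci_method = "delta")
  set.seed(101)
  mc <- compute_ic(tab, ci_method = "monte_carlo", n_mc = 50000)
  expect_lt(abs(delta$ci_low - mc$ci_low), 0.1)
  expect_lt(abs(delta$ci_high - mc$ci_high), 0.1)
})

test_that("PRR approaches ROR in the rare-event limit", {
  set.seed(3)
  for (k in 1:20) {
    a <- sample(3:30, 1); b <- sample(50:500, 1)
    c_ <- sample(5:50, 1); d <- sample(5e4:5e5, 1)
    prr <- compute_prr(c(a, b, c_, d))$prr
    ror <- compute_ror(c(a, b, c_, d))$ror
    expect_lt(abs(prr - ror) / ror, a / b + c_ / d)
  }
})

test_that("signal flags combine per the published criteria", {
  sulpiride <- c(12, 1383, 1503, 700948)
  flags <- evaluate_signals(compute_ror(sulpiride), compute_prr(sulpiride),
                            compute_ic(sulpiride))
  expect_true(flags[["ror_signal"]])
  expect_true(flags[["prr_signal"]])

  risperidone <- c(11, 2618, 1504, 701213)
  p <- compute_prr(risperidone)
  expect_lt(p$prr, 2)
  expect_false(p$signal)
  expect_true(compute_ror(risperidone)$signal)

  undef <- evaluate_signals(compute_ror(c(0, 1, 1, 1)),
                            compute_prr(c(0, 0, 1, 1)), NULL)
  expect_identical(unname(undef), c(FALSE, FALSE, FALSE))
})

test_that("screening returns one full-precision row per table", {
  db <- generate_cases(toy_config(n_cases = 2000, seed = 13))
  cases <- as_report_cases(db)
  tabs <- build_all(cases, c("drug_x", "drug_z"),
                    list(toy_set("event_y", 3), toy_set("event_z", 2)))
  scr <- screen_signals(tabs)
  expect_s3_class(scr, "signal_screen")
  expect_equal(nrow(scr), 4)
  expect_identical(scr$drug_name, sort(scr$drug_name))
  # build_all and the screen share the drug/event ordering
  expect_equal(scr$total, tabs$a + tabs$b)
  expect_equal(scr$n, tabs$a)

  # scalar and vectorized paths agree row by row
  k <- which(scr$drug_name == "drug_x" & scr$event_set_name == "event_y")
  tab_k <- tabs[tabs$drug_name == "drug_x" & tabs$event_set_name == "event_y", ]
  cells <- c(tab_k$a, tab_k$b, tab_k$c, tab_k$d)
  expect_equal(scr$ror[k], compute_ror(cells)$ror)
  expect_equal(scr$chi2[k], compute_prr(cells)$chi2)
  expect_equal(scr$ic[k], compute_ic(cells)$ic)

  expect_equal(nrow(screen_signals(list())), 0)
})
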