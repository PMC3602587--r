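test_that("doubling dilutions halve stepwise from the top dose", {
  d <- make_doubling_dilutions(400, 22)
  expect_equal(d[1:3], c(400, 200, 100))
  expect_equal(length(d), 22)
  expect_true(all(diff(d) < 0))
  expect_equal(make_doubling_dilutions(100, 12)[12], 100 / 2^11)
  expect_error(make_doubling_dilutions(10, 1), "at least 2")
  expect_error(make_doubling_dilutions(-5, 10), "positive")
})

test_that("4PL response is monotone with exact half-maximum at the midpoint", {
  cc <- make_doubling_dilutions(100, 12)
  for (h in c(0.5, 1, 2.5)) {
    y <- four_pl(cc, -5, 95, 3, h)
    expect_true(all(diff(y[order(cc)]) > 0))
    expect_equal(four_pl(3, -5, 95, 3, h), (95 - 5) / 2)
  }
})

test_that("noise-free 4PL data is recovered within 1%", {
  cc <- make_doubling_dilutions(100, 12)
  ft <- fit_4pl(cc, four_pl(cc, 0, 100, 10, 1))
  expect_lt(abs(ft$params$ic50 - 10) / 10, 0.01)
  expect_equal(ft$ic50$qualifier, "=")
  expect_false(ft$no_fit)
  expect_lt(abs(ft$params$hill - 1), 0.01)
})

test_that("curves peaking below 50% are censored above the top dose", {
  cc <- make_doubling_dilutions(100, 12)
  y <- four_pl(cc, 0, 40, 5, 1)          # max observed ~38%
  ft <- fit_4pl(cc, y)
  expect_equal(ft$ic50$qualifier, ">")
  expect_equal(ft$ic50$value, 100)
  expect_true(ft$partial)
})

test_that("degenerate inputs give no-fit flags or clear errors", {
  cc <- make_doubling_dilutions(100, 12)
  ft <- fit_4pl(cc, rep(20, 12))          # constant response
  expect_true(ft$no_fit)
  expect_null(ft$params)
  expect_equal(ft$ic50$qualifier, ">")
  expect_error(fit_4pl(c(1, 2, 4, 8), c(1, 2, 3, 4)), "at least 5")
})

test_that("partial-curve rule covers both the 65% and asymptote branches", {
  expect_false(flag_partial(90, top_dose_pct = 88, fitted_top = 90))
  expect_true(flag_partial(60))
  expect_true(flag_partial(80, top_dose_pct = 80, fitted_top = 95))
  expect_false(flag_partial(65, top_dose_pct = 64, fitted_top = 66))
})

test_that("censoring rule is strict below 50% with partial carried apart", {
  cv <- censor_ic50(8.6, 90)
  expect_equal(cv$qualifier, "=")
  expect_equal(cv$value, 8.6)
  cv2 <- censor_ic50(120, 40)
  expect_equal(cv2$qualifier, ">")
  expect_equal(cv2$value, 100)
  cv3 <- censor_ic50(33, 50)              # boundary: strictly "lower than 50"
  expect_equal(cv3$qualifier, "=")
  expect_equal(format_ic50(cv2, partial = TRUE), ">100*")
  expect_equal(format_ic50(censored_value("=", 8.6), FALSE), "8.6")
})

test_that("printed table entries parse back to censored values", {
  p <- parse_ic50_entry(c("24*", ">100", "8.6", ">100*"))
  expect_equal(p[[1]]$ic50$value, 24)
  expect_true(p[[1]]$partial)
  expect_equal(p[[2]]$ic50$qualifier, ">")
  expect_false(p[[2]]$partial)
  expect_equal(p[[3]]$ic50$value, 8.6)
  expect_true(p[[4]]$partial)
})

test_that("fold-shift algebra handles exact, censored and degenerate pairs", {
  # vincristine toward the uveal melanoma line: 0.040 -> >100
  fs <- fold_shift(censored_value("=", 0.040), censored_value(">"))
  expect_equal(fs$direction, "loss")
  expect_equal(fs$qualifier, ">")
  expect_equal(fs$magnitude, 2500)
  # berberine toward Y79: 24 -> 8.6, prints as "three fold"
  fs2 <- fold_shift(censored_value("=", 24), censored_value("=", 8.6))
  expect_equal(fs2$direction, "gain")
  expect_equal(fs2$qualifier, "=")
  expect_equal(fs2$magnitude, 24 / 8.6, tolerance = 1e-12)
  expect_equal(round(fs2$magnitude, 2), 2.79)
  # no change
  fs3 <- fold_shift(censored_value("=", 5), censored_value("=", 5))
  expect_equal(fs3$direction, "none")
  expect_equal(fs3$magnitude, 1)
  # both censored
  fs4 <- fold_shift(censored_value(">"), censored_value(">"))
  expect_equal(fs4$direction, "indeterminate")
  # censored reference, exact treatment: a gain bound
  fs5 <- fold_shift(censored_value(">"), censored_value("=", 20))
  expect_equal(fs5$direction, "gain")
  expect_equal(fs5$magnitude, 5)
  # vacuous bound when the exact operand exceeds the limit
  fs6 <- fold_shift(censored_value("=", 200), censored_value(">"))
  expect_equal(fs6$direction, "indeterminate")
})

test_that("swapping exact operands flips direction, preserves magnitude", {
  set.seed(14)
  for (i in 1:30) {
    a <- 10^runif(1, -2, 2); b <- 10^runif(1, -2, 2)
    f1 <- fold_shift(censored_value("=", a), censored_value("=", b))
    f2 <- fold_shift(censored_value("=", b), censored_value("=", a))
    expect_equal(f1$magnitude, f2$magnitude, tolerance = 1e-12)
    if (f1$direction != "none") {
      expect_equal(sort(c(f1$direction, f2$direction)), c("gain", "loss"))
    }
  }
})

test_that("censored fold magnitudes are true lower bounds", {
  set.seed(15)
  for (i in 1:30) {
    ref <- 10^runif(1, -2, 1.5)
    limit <- 100
    bound <- fold_shift(censored_value("=", ref),
                        censored_value(">", censor_limit = limit))$magnitude
    # brute-force substitution of any exact value beyond the limit
    for (v in limit * c(1.001, 2, 10, 500)) {
      exact <- fold_shift(censored_value("=", ref),
                          censored_value("=", v))$magnitude
      expect_gte(exact, bound)
    }
  }
})

test_that("modulation calls follow the two-fold rule at 80 uM", {
  # nocodazole: Y79 gains 6.1-fold but RB355 loses >90-fold; conflict
  # resolves to the larger magnitude
  sh <- rbind(
    data.frame(cell_line = "Y79", effector_uM = 80, direction = "gain",
               qualifier = "=", magnitude = 34 / 5.6),
    data.frame(cell_line = "RB355", effector_uM = 80, direction = "loss",
               qualifier = ">", magnitude = 100 / 1.1))
  mc <- classify_modulation(sh)
  expect_equal(mc$call, "antagonist_confirmed")
  expect_true(mc$conflict)

  # floxuridine viability: largest loss 1.7-fold, stays neutral
  sh2 <- rbind(
    data.frame(cell_line = "Y79", effector_uM = 80, direction = "loss",
               qualifier = "=", magnitude = 0.45 / 0.44),
    data.frame(cell_line = "RB355", effector_uM = 80, direction = "loss",
               qualifier = "=", magnitude = 1.4 / 0.82))
  expect_equal(classify_modulation(sh2)$call, "neutral")

  sh3 <- data.frame(cell_line = "Y79", effector_uM = 80, direction = "none",
                    qualifier = "=", magnitude = 1)
  expect_equal(classify_modulation(sh3)$call, "neutral")
  expect_error(classify_modulation(sh3[0, ]), "empty")
})

test_that("raising the fold threshold never adds confirmed calls", {
  set.seed(16)
  for (i in 1:20) {
    sh <- data.frame(cell_line = sample(c("A", "B"), 6, TRUE),
                     effector_uM = 80,
                     direction = sample(c("gain", "loss", "none"), 6, TRUE),
                     qualifier = "=",
                     magnitude = 10^runif(6, 0, 1.5))
    prev <- classify_modulation(sh, fold_threshold = 2)$call != "neutral"
    for (thr in c(3, 5, 10, 50)) {
      cur <- classify_modulation(sh, fold_threshold = thr)$call != "neutral"
      expect_true(prev || !cur)
      prev <- cur
    }
  }
})

test_that("panel confirmation needs three qualifying non-retinoblastoma lines", {
  lines <- data.frame(cell_line = c("rb1", "rb2", "n1", "n2", "n3", "n4", "n5"),
                      retinoblastoma = c(TRUE, TRUE, rep(FALSE, 5)))
  mk <- function(cl, mag) {
    data.frame(compound_id = "x", cell_line = cl, effector_uM = 80,
               direction = "gain", qualifier = "=", magnitude = mag)
  }
  # qualifying in 3 of 5 non-retinoblastoma lines
  sh <- rbind(mk("n1", 4), mk("n2", 3), mk("n3", 2.2), mk("n4", 1.1),
              mk("rb1", 5))
  pp <- panel_profile(sh, lines, direction = "gain")
  expect_true(pp$summary$panel_confirmed)
  expect_equal(pp$summary$n_qualifying_nonrb, 3)
  # 2 non-retinoblastoma + 2 retinoblastoma is not enough
  sh2 <- rbind(mk("n1", 4), mk("n2", 3), mk("rb1", 5), mk("rb2", 5))
  expect_false(panel_profile(sh2, lines, direction = "gain")$summary$panel_confirmed)
  expect_error(panel_profile(mk("unknown", 4), lines, direction = "gain"),
               "without retinoblastoma label")
})

test_that("noise-free parameter recovery holds across the bracketed range", {
  cc <- make_doubling_dilutions(100, 12)
  set.seed(17)
  for (i in 1:20) {
    ic <- 10^runif(1, log10(0.1), log10(50))
    h <- runif(1, 0.5, 3)
    ft <- fit_4pl(cc, four_pl(cc, 0, 100, ic, h))
    expect_lt(abs(ft$params$ic50 - ic) / ic, 0.01)
  }
})
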