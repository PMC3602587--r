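test_that("generators are bit-reproducible for a fixed seed", {
  a <- generate_screen(200, c(agonist = 5), noise_model(cv = 7, seed = 42))
  b <- generate_screen(200, c(agonist = 5), noise_model(cv = 7, seed = 42))
  expect_identical(a, b)
  c <- generate_screen(200, c(agonist = 5), noise_model(cv = 7, seed = 43))
  expect_false(identical(a$plates$signal, c$plates$signal))

  i1 <- generate_nuclei_image(20, seed = 7)
  i2 <- generate_nuclei_image(20, seed = 7)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("control-run generator recovers its target means", {
  # noise-free: exact means, perfect separation
  p0 <- generate_control_run(14426, 1483, noise_model(cv = 0), 3)
  st0 <- control_stats(p0)
  expect_equal(st0$mu_high, 14426)
  expect_equal(st0$mu_low, 1483)
  expect_equal(zprime(st0), 1)

  # 5% CV over 1,152 wells per role: means within 1%
  p <- generate_control_run(14426, 1483, noise_model(cv = 5, seed = 11), 3)
  st <- control_stats(p)
  expect_equal(st$n_high, 1152)
  expect_lt(abs(st$mu_high - 14426) / 14426, 0.01)
  expect_lt(abs(st$mu_low - 1483) / 1483, 0.01)
  # empirical CV matches the noise model within sampling error
  expect_lt(abs(st$cv_high - 5), 0.75)
  expect_lt(abs(st$cv_low - 5), 0.75)

  expect_equal(nrow(generate_control_run(100, 10, n_plates = 0)), 0)
  expect_error(generate_control_run(10, 100), "mu_high > mu_low")
})

test_that("screen generator plants classes with the stated margin", {
  scr <- generate_screen(500, c(agonist = 20, antagonist = 20,
                                potent_both = 10),
                         noise_model(cv = 0, seed = 4), margin = 15)
  tr <- scr$truth
  for (line in c("Y79", "RB355")) {
    plus <- tr[[paste0("pct_", line, "_plus")]]
    minus <- tr[[paste0("pct_", line, "_minus")]]
    expect_true(all(plus[tr$class == "agonist"] >= 65))
    expect_true(all(minus[tr$class == "agonist"] <= 35))
    expect_true(all(minus[tr$class == "antagonist"] >= 65))
    expect_true(all(plus[tr$class == "antagonist"] <= 35))
    expect_true(all(pmax(plus, minus)[tr$class == "inactive"] <= 35))
    expect_true(all(pmin(plus, minus)[tr$class == "potent_both"] >= 65))
  }
  expect_error(generate_screen(10, c(agonist = 11)), "exceed")
})

test_that("an all-inactive screen yields zero candidates", {
  scr <- generate_screen(352, c(agonist = 0), noise_model(cv = 0, seed = 6))
  prof <- screen_profiles(scr$plates)
  expect_false(any(prof$class %in%
                     c("agonist_candidate", "antagonist_candidate")))
})

test_that("dose-response generator round-trips planted truths", {
  design <- make_doubling_dilutions(100, 12)
  truth <- data.frame(compound_id = "x", cell_line = "L", effector_uM = 0,
                      bottom = 0, top = 100, ic50 = 10, hill = 1,
                      noise_sd = 0)
  dr <- generate_dose_response(truth, design, n_reps = 2, seed = 1)
  ft <- fit_4pl(dr$conc_uM, dr$pct_inhibition)
  expect_lt(abs(ft$params$ic50 - 10) / 10, 0.01)

  # planted 20-fold loss under the effector confirms as antagonist
  truth2 <- rbind(truth,
                  within(truth, { effector_uM <- 80; ic50 <- 200 }))
  dr2 <- generate_dose_response(truth2, design, n_reps = 2, seed = 1)
  res <- lapply(split(dr2, dr2$effector_uM), function(d) {
    ft <- fit_4pl(d$conc_uM, d$pct_inhibition, censor_limit = 100)
    ft$ic50
  })
  fs <- fold_shift(res[["0"]], res[["80"]])
  expect_equal(fs$direction, "loss")
  expect_gte(fs$magnitude, 2)
  mc <- classify_modulation(data.frame(
    cell_line = "L", effector_uM = 80, direction = fs$direction,
    qualifier = fs$qualifier, magnitude = fs$magnitude))
  expect_equal(mc$call, "antagonist_confirmed")

  # a truth that never reaches 50% is censored at the top dose
  truth3 <- within(truth, top <- 40)
  dr3 <- generate_dose_response(truth3, design, n_reps = 1, seed = 2)
  ft3 <- fit_4pl(dr3$conc_uM, dr3$pct_inhibition)
  expect_equal(ft3$ic50$qualifier, ">")
  expect_equal(ft3$ic50$value, 100)
})

test_that("turbidity generator plants a detectable solubility limit", {
  tb <- generate_turbidity(limit = 400, seed = 3)
  sl <- solubility_limit(tb$concentrations, tb$turbidity, tb$baseline_values)
  expect_equal(sl$threshold, 20)
  expect_equal(sl$limit, 400)
  expect_equal(sl$limit, tb$limit_planted)

  # limit above the tested range: nothing precipitates
  tb2 <- generate_turbidity(limit = 20000,
                            design = make_doubling_dilutions(6400, 24),
                            seed = 3)
  sl2 <- solubility_limit(tb2$concentrations, tb2$turbidity,
                          tb2$baseline_values)
  expect_true(is.na(sl2$limit))

  # zero baseline spread collapses the threshold onto the mean
  tb3 <- generate_turbidity(limit = 400, baseline_sd = 0, seed = 3)
  sl3 <- solubility_limit(tb3$concentrations, tb3$turbidity,
                          tb3$baseline_values)
  expect_equal(sl3$threshold, 4)
  expect_error(generate_turbidity(limit = 1e-5), "below the tested range")
})

test_that("growth generator plants the narrative seeding selection", {
  curves <- generate_growth(densities = c(4000, 32000),
                            linear_until = c(`4000` = 120, `32000` = 48))
  expect_equal(assess_growth(curves)$selected_density, 4000)
  none <- generate_growth(densities = c(8000, 32000),
                          linear_until = c(`8000` = 48, `32000` = 48))
  expect_true(is.na(assess_growth(none)$selected_density))
})

test_that("nuclei-image generator output is counted at its planted truth", {
  for (seed in c(1, 5, 9)) {
    im <- generate_nuclei_image(50, radius = 6, overlap_fraction = 0,
                                size = 300, seed = seed)
    expect_equal(segment_nuclei(im$pixels)$count, 50)
  }
  expect_error(generate_nuclei_image(5000, radius = 10, size = 100, seed = 1),
               "infeasible packing")
})

test_that("overlapping nuclei counts stay within 10% with clump breaking", {
  counts <- vapply(1:20, function(seed) {
    im <- generate_nuclei_image(20, radius = 6, overlap_fraction = 0.3,
                                size = 256, seed = seed)
    segment_nuclei(im$pixels, clump_breaking = TRUE)$count
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20) / 20, 0.1)
})
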