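test_that("control stats pool wells per role with sample-SD denominator", {
  plates <- rbind(
    generate_control_run(14426, 1483, noise_model(cv = 0), 3))
  st <- control_stats(plates)
  expect_equal(st$n_high, 1152)
  expect_equal(st$n_low, 1152)
  expect_equal(st$mu_high, 14426)
  expect_equal(st$mu_low, 1483)
  expect_equal(st$sd_high, 0)
  expect_equal(st$sd_low, 0)

  two <- data.frame(role = rep(c("high_control", "low_control"), each = 2),
                    signal = c(10, 12, 1, 3))
  st2 <- control_stats(two)
  expect_equal(st2$sd_high, sd(c(10, 12)))   # n-1 denominator
  expect_equal(st2$cv_high, 100 * sd(c(10, 12)) / 11)

  one <- data.frame(role = c("high_control", "low_control", "low_control"),
                    signal = c(10, 1, 2))
  expect_error(control_stats(one), "high_control")
})

test_that("Z' follows its closed form and boundary behaviour", {
  mk <- function(mh, sh, ml, sl) {
    list(mu_high = mh, sd_high = sh, mu_low = ml, sd_low = sl)
  }
  expect_equal(zprime(mk(10, 1, 0, 1)), 0.4)
  expect_equal(zprime(mk(100, 0, 10, 0)), 1)
  expect_error(zprime(mk(5, 1, 5, 1)), "equal")
  # decreases as either SD grows
  expect_lt(zprime(mk(10, 2, 0, 1)), zprime(mk(10, 1, 0, 1)))
  expect_lt(zprime(mk(10, 1, 0, 2)), zprime(mk(10, 1, 0, 1)))
})

test_that("Z' is affine-invariant and never exceeds 1", {
  set.seed(31)
  for (i in 1:25) {
    hi <- rnorm(20, 100, runif(1, 0, 20))
    lo <- rnorm(20, runif(1, 0, 50), runif(1, 0, 20))
    st <- control_stats(data.frame(
      role = rep(c("high_control", "low_control"), each = 20),
      signal = abs(c(hi, lo))))
    z <- zprime(st)
    expect_lte(z, 1)
    a <- runif(1, 0.1, 10); b <- runif(1, 0, 1000)
    st2 <- control_stats(data.frame(
      role = rep(c("high_control", "low_control"), each = 20),
      signal = a * abs(c(hi, lo)) + b))
    expect_equal(zprime(st2), z, tolerance = 1e-9)
  }
})

test_that("S/N is the plain mean ratio; only the report label rounds", {
  st <- list(mu_high = 14426, mu_low = 1483)
  sn <- signal_to_noise(st)
  expect_equal(sn$ratio, 14426 / 1483)
  expect_equal(sn$label, "10:1")
  sn2 <- signal_to_noise(list(mu_high = 8065, mu_low = 2557))
  expect_equal(sn2$ratio, 8065 / 2557, tolerance = 1e-12)
  expect_equal(sn2$label, "3:1")
  expect_equal(signal_to_noise(list(mu_high = 5, mu_low = 5))$ratio, 1)
  expect_error(signal_to_noise(list(mu_high = 5, mu_low = 0)), "S/N")
})

test_that("robustness gate is strict at 0.5 with narrative bands", {
  g <- qc_gate(0.79)
  expect_true(g$robust)
  expect_equal(g$band, "excellent")
  g2 <- qc_gate(0.22)
  expect_false(g2$robust)
  expect_equal(g2$band, "poor")
  g3 <- qc_gate(0.5)
  expect_false(g3$robust)       # strict inequality
  expect_equal(qc_gate(0.56)$band, "good")
})

test_that("growth assessment selects the linear density with widest window", {
  curves <- generate_growth(
    densities = c(2000, 4000, 32000),
    linear_until = c(`2000` = 120, `4000` = 120, `32000` = 48))
  res <- assess_growth(curves)
  expect_equal(res$selected_density, 4000)
  per <- res$per_density
  expect_true(all(per$r2[per$density %in% c(2000, 4000)] == 1))
  expect_false(per$linear[per$density == 32000])
})

test_that("a saturating series fails the linearity threshold (direct R^2)", {
  t <- c(24, 48, 72, 96, 120)
  s <- c(24, 48, 48, 48, 48)   # plateau from 48 h
  r2_direct <- cor(t, s)^2
  expect_lt(r2_direct, 0.95)
  res <- assess_growth(data.frame(density = 1000, time_h = t, signal = s))
  expect_equal(res$per_density$r2, r2_direct, tolerance = 1e-12)
  expect_false(res$per_density$linear)
  expect_true(is.na(res$selected_density))
})

test_that("exactly linear synthetic curves give R^2 = 1 for every density", {
  curves <- generate_growth(densities = c(1000, 4000, 8000),
                            linear_until = 120)
  res <- assess_growth(curves)
  expect_true(all(res$per_density$r2 == 1))
  expect_true(all(res$per_density$linear))
})

test_that("flat growth curves are flagged rather than fitted", {
  curves <- generate_growth(densities = c(1000, 2000), rate = 0)
  res <- assess_growth(curves)
  expect_true(all(is.na(res$per_density$r2)))
  expect_true(is.na(res$selected_density))
})

test_that("solubility threshold is baseline mean + 3 SD", {
  # mean 4 NTU with SD 16/3 gives the canonical 20 NTU threshold
  baseline <- 4 + c(-1, 0, 1) * 16 / 3
  expect_equal(mean(baseline), 4)
  expect_equal(sd(baseline), 16 / 3)
  res <- solubility_limit(c(100, 200, 400, 800), c(4, 4, 30, 60), baseline)
  expect_equal(res$threshold, 20)
  expect_equal(res$limit, 400)
})

test_that("solubility crossing must be sustained at higher concentrations", {
  baseline <- c(3, 4, 5)
  thr <- mean(baseline) + 3 * sd(baseline)
  # single spike at 200 that is not sustained: limit set by the true crossing
  res <- solubility_limit(c(100, 200, 400, 800, 1600),
                          c(1, thr + 5, 1, thr + 5, thr + 10), baseline)
  expect_equal(res$limit, 800)
  # nothing exceeds
  res2 <- solubility_limit(c(100, 200), c(1, 2), baseline)
  expect_true(is.na(res2$limit))
  expect_equal(res2$limit_label, "above tested range")
  expect_error(solubility_limit(c(-1, 2), c(1, 2), baseline), "positive")
})

test_that("adding above-threshold turbidity at higher doses never raises the limit", {
  baseline <- c(3, 4, 5)
  thr <- mean(baseline) + 3 * sd(baseline)
  conc <- c(100, 200, 400, 800)
  turb <- c(1, 1, thr + 10, thr + 10)
  base_limit <- solubility_limit(conc, turb, baseline)$limit
  turb2 <- turb
  turb2[2] <- thr + 20            # extend exceedance downward
  expect_lte(solubility_limit(conc, turb2, baseline)$limit, base_limit)
})
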