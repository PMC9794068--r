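test_that("daily mortality probability reproduces the published conversions", {
  # (1 - m) = (1 - p)^d for the three lethality classes over 7 days
  expect_equal(round(daily_mortality_prob(0.90, 7), 2), 0.28)
  expect_equal(round(daily_mortality_prob(0.50, 7), 2), 0.09)
  expect_equal(round(daily_mortality_prob(0.25, 7), 2), 0.04)
  expect_equal(daily_mortality_prob(0, 7), 0)

  # exact inversion to machine precision
  for (m in c(0.25, 0.5, 0.9, 0.99)) {
    p <- daily_mortality_prob(m, 7)
    expect_equal((1 - p)^7, 1 - m, tolerance = 1e-14)
  }
  expect_error(daily_mortality_prob(-0.1, 7), "must be in")
  expect_error(daily_mortality_prob(1.1, 7), "must be in")
  expect_error(daily_mortality_prob(0.5, 0.5), "d must be")
  expect_warning(p1 <- daily_mortality_prob(1, 7), "degenerate")
  expect_equal(p1, 1)
})

test_that("temperature adjustment of the half-life follows the Q10 rule", {
  expect_equal(temperature_adjusted_dt50(25, 20), 25)
  expect_equal(temperature_adjusted_dt50(25, 10), 25 * 2.58)
  expect_equal(temperature_adjusted_dt50(1.3, 30), 1.3 / 2.58)
  # decreasing in temperature
  t <- seq(-5, 30, by = 5)
  dt <- temperature_adjusted_dt50(25, t)
  expect_true(all(diff(dt) < 0))
  expect_error(temperature_adjusted_dt50(0, 10), "> 0")
})

test_that("toxic-unit treatment rates match the calibration intent", {
  expect_equal(round(treatment_rate(1.3, 7), 2), 41.78)
  # slow-decay product: formula gives 1.21 (the source prints 1.22; the
  # 0.01 gap is a rounding artefact documented, not asserted)
  expect_equal(round(treatment_rate(25, 7), 2), 1.21)
  expect_equal(treatment_rate(1e12, 7), 1, tolerance = 1e-9)

  # closed-form half-life oracle: rate * 0.5^(d / dt50) == trigger exactly
  for (dt50 in c(1.3, 25)) {
    rate <- treatment_rate(dt50, 7)
    expect_equal(rate * 0.5^(7 / dt50), 1.0, tolerance = 1e-12)
  }
})

test_that("a treatment-rate deposit crosses the trigger after the effect period", {
  g <- uniform_field_grid(5)
  for (dt50 in c(1.3, 25)) {
    prod <- pesticide_product("LR90", dt50_20 = dt50)
    expo <- new_exposure_grid(g)
    expo$conc[3, 3] <- prod$treatment_rate
    for (day in 1:7) expo <- daily_decay(expo, 20, prod)
    # still at the trigger on day 7 (the calibration intent) ...
    expect_equal(expo$conc[3, 3], 1.0, tolerance = 1e-9)
    # ... and clearly below it on day 8
    expo <- daily_decay(expo, 20, prod)
    expect_lt(expo$conc[3, 3], 1 - 1e-3)
  }
  # zero stays zero; halving time at 20 C equals the nominal DT50
  prod <- pesticide_product("LR90", dt50_20 = 5)
  expo <- new_exposure_grid(g)
  expo$conc[1, 1] <- 8; expo$conc[2, 2] <- 0
  for (i in 1:5) expo <- daily_decay(expo, 20, prod)
  expect_equal(expo$conc[1, 1], 4, tolerance = 1e-12)
  expect_equal(expo$conc[2, 2], 0)
})

test_that("drift curve has the published coefficients and cut-off", {
  cv <- drift_curve()
  expect_equal(drift_fraction(1, cv), 2.7705)
  expect_equal(drift_fraction(13, cv), 0)
  expect_equal(drift_fraction(12.01, cv), 0)
  d <- seq(0.5, 12, by = 0.25)
  expect_true(all(diff(drift_fraction(d, cv)) < 0))
  # drift reduction scales deposition multiplicatively
  cv90 <- drift_curve(reduction = 0.9)
  expect_equal(drift_fraction(5, cv90), 0.1 * drift_fraction(5, cv),
               tolerance = 1e-12)
  expect_error(drift_fraction(0, cv), "dist must be")
  expect_error(drift_fraction(-1, cv), "dist must be")
})

test_that("application deposits the treatment rate in-field and drift off-field", {
  # 20 x 20 field embedded in a 46 x 46 non-field grid, 1-m cells
  el <- matrix("herbaceous_seminatural", 46, 46)
  fid <- matrix(0L, 46, 46)
  el[13:32, 13:32] <- "arable_field"; fid[13:32, 13:32] <- 1L
  g <- make_test_grid(el, fid)
  prod <- pesticide_product("LR90", dt50_20 = 1.3)
  cv <- drift_curve(reduction = 0.5)
  expo <- apply_application(new_exposure_grid(g), g, 1L, prod, cv)

  # sprayed cells carry exactly the treatment rate (>= trigger)
  expect_true(all(expo$conc[13:32, 13:32] == prod$treatment_rate))
  expect_gte(min(expo$conc[13:32, 13:32]), 1.0)

  # first off-field ring: centre is 0.5 m from the field edge
  expected_ring <- prod$treatment_rate *
    (1 - 0.5) * 2.7705 * 0.5^(-0.9787) / 100
  expect_equal(expo$conc[12, 20], expected_ring, tolerance = 1e-12)
  expect_equal(expo$conc[20, 33], expected_ring, tolerance = 1e-12)

  # deposition reaches exactly 12 m and no further
  expect_gt(expo$conc[1, 20], 0)          # 11.5 m from the edge
  expect_equal(expo$conc[45, 20], 0)      # 12.5 m, beyond the cut-off
  # strictly decreasing along a transect away from the field
  transect <- expo$conc[11:1, 20]
  expect_true(all(diff(transect) <= 0))
  expect_true(all(transect[1:11] < prod$treatment_rate))

  expect_error(apply_application(expo, g, 99L, prod, cv), "unknown field")
})

test_that("margins are not sprayed but do receive drift", {
  g <- uniform_field_grid(30, cell_size = 1)
  gm <- add_field_margins(g, 1, width_m = 4, seed = 1)
  prod <- pesticide_product("LR90", dt50_20 = 1.3)
  expo <- apply_application(new_exposure_grid(gm), gm, 1L, prod,
                            drift_curve())
  margin <- gm$element == element_code("field_margin")
  crop <- gm$element == element_code("arable_field")
  expect_true(all(expo$conc[crop] == prod$treatment_rate))
  expect_true(all(expo$conc[margin] < prod$treatment_rate))
  expect_true(any(expo$conc[margin] > 0))
})

test_that("trigger mortality has a hard threshold and no dose-response", {
  prod <- pesticide_product("LR90")
  # below the trigger: always survives
  set.seed(1)
  expect_true(!any(exposure_mortality(rep(0.99, 1000), prod)))
  # no dose-response: identical RNG stream gives identical outcomes at
  # 1.5 and at 10 toxic units
  set.seed(42); a <- exposure_mortality(rep(1.5, 1000), prod)
  set.seed(42); b <- exposure_mortality(rep(10, 1000), prod)
  expect_identical(a, b)
  expect_gt(mean(a), 0.2)
})
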