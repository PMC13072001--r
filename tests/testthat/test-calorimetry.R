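t0 <- utc("2025-01-06 00:00:00")

test_that("Brouwer heat production evaluates the printed coefficients exactly", {
  expect_equal(brouwer_thp(0, 0, 0, 0), 0)
  # direct evaluation: 16.18*100 + 5.02*90 - 2.17*1 - 5.99*5
  expect_equal(brouwer_thp(100, 90, 1, 5), 2037.68)
  expect_equal(brouwer_thp(1000, 900, 0, 0), 10 * brouwer_thp(100, 90, 0, 0))
})

test_that("Brouwer equation is exactly linear (superposition)", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(4, 0, 500); b <- runif(4, 0, 500); w <- runif(2, -2, 2)
    combo <- suppressWarnings(
      brouwer_thp(w[1] * a[1] + w[2] * b[1], w[1] * a[2] + w[2] * b[2],
                  w[1] * a[3] + w[2] * b[3], w[1] * a[4] + w[2] * b[4]))
    parts <- suppressWarnings(
      w[1] * brouwer_thp(a[1], a[2], a[3], a[4]) +
        w[2] * brouwer_thp(b[1], b[2], b[3], b[4]))
    expect_equal(combo, parts, tolerance = 1e-12)
  }
  expect_warning(brouwer_thp(-1, 0), "negative")
  expect_error(brouwer_thp(Inf, 0), "finite")
})

test_that("trapezoidal gas integration is exact for constant and linear traces", {
  # constant O2 uptake 0.005 at 500 L/min for 24 h -> 3600 L
  rec <- constant_trace(t0, 1440, o2 = 0.005, co2 = 0.0048)
  v <- integrate_gas_day(rec, t0, t0 + 86400)
  expect_equal(v$vo2_l, 0.005 * 500 * 1440)
  expect_equal(v$vco2_l, 0.0048 * 500 * 1440)
  expect_equal(v$coverage, 1)

  # zero flow -> zero volumes
  rec0 <- constant_trace(t0, 1440, o2 = 0.005, flow = 0)
  v0 <- integrate_gas_day(rec0, t0, t0 + 86400)
  expect_equal(c(v0$vo2_l, v0$vco2_l, v0$vch4_l), c(0, 0, 0))

  # linear concentration ramp, constant flow: trapezoid equals the
  # closed-form integral flow * (a*T + b*T^2/2)
  minutes <- 0:480
  a <- 0.004; b <- 1e-6; flow <- 350
  rec_lin <- data.frame(sow_id = "S1", timestamp = t0 + 60 * minutes,
                        o2_conc = a + b * minutes, co2_conc = 0,
                        ch4_conc = 0, flow_l_min = flow, state = "fed")
  v_lin <- integrate_gas_day(rec_lin, t0, t0 + 480 * 60)
  expect_equal(v_lin$vo2_l, flow * (a * 480 + b * 480^2 / 2),
               tolerance = 1e-9)
})

test_that("integration handles windows, gaps, and negative volumes", {
  rec <- constant_trace(t0, 1440, o2 = 0.005)
  expect_error(integrate_gas_day(rec, t0, t0), "empty window")
  expect_error(integrate_gas_day(rec[1, ], t0, t0 + 3600), ">= 2 gas records")

  # a one-hour hole in the trace breaks coverage
  holey <- rec[!(rec$timestamp > t0 + 3600 & rec$timestamp < t0 + 7200), ]
  expect_warning(v <- integrate_gas_day(holey, t0, t0 + 86400),
                 "gaps exceed")
  expect_lt(v$coverage, 1)

  # negative concentration difference (calibration drift) is flagged, kept
  drift <- constant_trace(t0, 60, o2 = -0.001)
  expect_warning(vn <- integrate_gas_day(drift, t0, t0 + 3600),
                 "calibration drift")
  expect_lt(vn$vo2_l, 0)
})

test_that("respiratory quotient is the CO2/O2 ratio with a guarded domain", {
  expect_equal(respiratory_quotient(100, 100), 1)
  expect_equal(respiratory_quotient(200, 160), 0.8)
  expect_error(respiratory_quotient(0, 10), "vo2")
})

test_that("fasting heat production recovers the generator's ground truth", {
  truth <- trial_ground_truth(seed = 5, n_ingredients = 1, sows_per_diet = 1,
                              noise = noiseless_cv)
  one <- simulate_sow_period(truth$sows[1, ], truth$diets[1, ],
                             noise = noiseless_cv)
  sp <- one$sow_period
  fast_gas <- one$gas[one$gas$state == "fasted", ]
  urine_fast <- one$collections[one$collections$kind == "urine" &
                                  one$collections$state == "fasted", ]
  fhp <- fasting_heat_production(fast_gas, sp$fast_start, sp$fast_end,
                                 urinary_n_g = urine_fast$n_g_d,
                                 bw_kg = sp$bw_kg)
  expect_equal(fhp$fhp_kj_kg075_d, truth$sows$fhp_kj_kg075[1],
               tolerance = 1e-9)
  expect_gte(fhp$rq, 0.76)
  expect_lte(fhp$rq, 0.83)
})

test_that("fasting heat production is linear in the gas volumes", {
  fs <- t0 + 22 * 3600
  fe <- fs + 8 * 3600
  rec <- constant_trace(fs, 480, o2 = 0.004, co2 = 0.0032, state = "fasted")
  f1 <- fasting_heat_production(rec, fs, fe, urinary_n_g = 0, bw_kg = 213)
  rec2 <- rec
  rec2$o2_conc <- 2 * rec2$o2_conc
  rec2$co2_conc <- 2 * rec2$co2_conc
  f2 <- fasting_heat_production(rec2, fs, fe, urinary_n_g = 0, bw_kg = 213)
  expect_equal(f2$fhp_kj_kg075_d, 2 * f1$fhp_kj_kg075_d, tolerance = 1e-12)
  # the 8 h window is extrapolated linearly to a daily rate
  expect_equal(f1$thp_kj_d,
               brouwer_thp(f1$vo2_l, f1$vco2_l, f1$vch4_l, 0) * 3,
               tolerance = 1e-9)
})

test_that("insufficient fasting-window coverage is a quality error", {
  fs <- t0 + 22 * 3600
  fe <- fs + 8 * 3600
  rec <- constant_trace(fs, 480, o2 = 0.004, co2 = 0.0032, state = "fasted")
  truncated <- rec[rec$timestamp <= fs + 4 * 3600, ]
  expect_error(
    suppressWarnings(fasting_heat_production(truncated, fs, fe,
                                             urinary_n_g = 0, bw_kg = 213)),
    "coverage")
})

test_that("daily calorimetry summaries satisfy the type identities", {
  day <- calorimetry_day("S1", "2025-01-06", "fed", vo2_l = 3600,
                         vco2_l = 3500, vch4_l = 8, urinary_n_g = 2.9)
  expect_equal(day$rq, 3500 / 3600, tolerance = 1e-12)
  expect_equal(day$thp_kj,
               brouwer_thp(3600, 3500, 8, 2.9), tolerance = 1e-12)
})
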