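# Weather forcing, scenarios, bulb pseudo-observations.

test_that("a noiseless series hits the configured daily extremes exactly", {
  w <- flat_weather(3, tmax = 30, tmin = 20)
  d <- as.Date(w$timestamp)
  expect_equal(as.numeric(tapply(w$Tair_C, d, max)), rep(30, 3),
               tolerance = 1e-6)
  expect_equal(as.numeric(tapply(w$Tair_C, d, min)), rep(20, 3),
               tolerance = 1e-6)
})

test_that("solar radiation is zero at night and nonnegative always", {
  w <- generate_weather(5, month_start = 6, seed = 2)
  hh <- as.integer(strftime(w$timestamp, "%H", tz = "UTC"))
  expect_true(all(w$solar_Wm2[hh %in% c(0, 1, 2, 3, 22, 23)] == 0))
  expect_true(all(w$solar_Wm2 >= 0))
  expect_true(all(w$RH_pct >= 0 & w$RH_pct <= 100))
  expect_true(all(w$wind_ms >= 0))
})

test_that("mean January daily maximum matches the site climatology", {
  means <- vapply(1:100, function(s) {
    w <- generate_weather(31, month_start = 1, seed = s)
    mean(tapply(w$Tair_C, as.Date(w$timestamp), max))
  }, numeric(1))
  expect_equal(mean(means), 32.6, tolerance = 1)
})

test_that("seasonality is in the southern hemisphere's phase", {
  wj <- flat_weather(5, 32, 20)  # parameters irrelevant here
  wjan <- generate_weather(10, month_start = 1, seed = 1)
  wjun <- generate_weather(10, month_start = 6, seed = 1)
  expect_gt(mean(wjan$Tair_C), mean(wjun$Tair_C))
  expect_gt(max(wjan$solar_Wm2), max(wjun$solar_Wm2))
})

test_that("a null scenario is the identity and deltas act additively", {
  w <- generate_weather(4, month_start = 10, seed = 3)
  s0 <- climate_scenario(0, rh_scale = 1)
  w0 <- apply_scenario(w, s0)
  expect_equal(w0$Tair_C, w$Tair_C)
  expect_equal(w0$RH_pct, w$RH_pct)

  s4 <- climate_scenario(4)
  w4 <- apply_scenario(w, s4)
  expect_equal(w4$Tair_C, w$Tair_C + 4)
  expect_equal(w4$solar_Wm2, w$solar_Wm2)
  expect_equal(w4$wind_ms, w$wind_ms)
  expect_equal(nrow(w4), nrow(w))
})

test_that("humidity scaling clamps at 100%", {
  w <- generate_weather(2, month_start = 12, seed = 4)
  w$RH_pct[1] <- 80
  ws <- apply_scenario(w, climate_scenario(0, rh_scale = 1.5))
  expect_equal(ws$RH_pct[1], 100)
  expect_true(all(ws$RH_pct <= 100))
})

test_that("monthly deltas are applied by calendar month", {
  w <- generate_weather(62, month_start = 10, seed = 5)  # Oct + Nov
  deltas <- c(rep(0, 9), 2, 5, 0)
  ws <- apply_scenario(w, climate_scenario(deltas))
  m <- as.integer(strftime(w$timestamp, "%m", tz = "UTC"))
  expect_equal(ws$Tair_C[m == 10], w$Tair_C[m == 10] + 2)
  expect_equal(ws$Tair_C[m == 11], w$Tair_C[m == 11] + 5)
})

test_that("noise-free bulb observations reproduce the series at sample times", {
  w <- generate_weather(2, month_start = 1, seed = 6)
  true_te <- data.frame(timestamp = w$timestamp, Te_C = w$Tair_C)
  obs <- generate_bulb_observations(true_te, noise_sd = 0,
                                    logger_interval_min = 60, seed = 1)
  expect_equal(obs$Te_C, true_te$Te_C)
  # 20-min logging triples the sampling density (interpolated)
  obs20 <- generate_bulb_observations(true_te, noise_sd = 0,
                                      logger_interval_min = 20, seed = 1)
  expect_equal(nrow(obs20), 3L * (nrow(true_te) - 1L) + 1L)
  expect_equal(obs20$Te_C[seq(1, nrow(obs20), by = 3)], true_te$Te_C)
  # determinism
  o1 <- generate_bulb_observations(true_te, 0.4, 20, seed = 9)
  o2 <- generate_bulb_observations(true_te, 0.4, 20, seed = 9)
  expect_identical(o1, o2)
})

test_that("KS comparison of noisy vs true daily maxima behaves as the
           Monte-Carlo oracle predicts", {
  # At low logger noise the distributions of daily maxima are
  # indistinguishable in essentially every replicate; at 0.5 degC the iid
  # per-sample noise inflates daily maxima by ~0.55 degC (max of ~7 draws
  # near the diurnal peak), a shift the KS test detects about half the
  # time at n = 90. Both rates were computed with this same oracle.
  w <- generate_weather(90, month_start = 12, seed = 42)
  true_te <- data.frame(timestamp = w$timestamp, Te_C = w$Tair_C)
  td <- as.numeric(tapply(true_te$Te_C, as.Date(true_te$timestamp), max))
  rate <- function(noise_sd, seeds) {
    ok <- vapply(seeds, function(s) {
      obs <- generate_bulb_observations(true_te, noise_sd, 20, seed = s)
      od <- as.numeric(tapply(obs$Te_C, as.Date(obs$timestamp), max))
      ks_two_sample(td, od)$p_value >= 0.05
    }, logical(1))
    mean(ok)
  }
  expect_gte(rate(0.25, 1:100), 0.9)
  r5 <- rate(0.5, 1:200)
  expect_gte(r5, 0.35)
  expect_lte(r5, 0.65)
})

test_that("weather CSV round-trips with ISO-8601 timestamps", {
  w <- generate_weather(2, month_start = 3, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(as.numeric(w2$timestamp), as.numeric(w$timestamp))
  expect_equal(w2$Tair_C, w$Tair_C, tolerance = 1e-8)
})
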