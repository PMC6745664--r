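test_that("weather generation is bit-reproducible from its seed", {
  cfg <- weather_config()
  a <- generate_weather(cfg, years = 2, seed = 12)
  b <- generate_weather(cfg, years = 2, seed = 12)
  expect_identical(as.numeric(a$temp), as.numeric(b$temp))
  expect_identical(as.numeric(a$precip), as.numeric(b$precip))
  c_ <- generate_weather(cfg, years = 2, seed = 13)
  expect_false(identical(as.numeric(a$precip), as.numeric(c_$precip)))
})

test_that("generated climate matches the configured Mediterranean regime", {
  cfg <- weather_config()
  expect_equal(expected_annual_precipitation(cfg), cfg$annual_p,
               tolerance = 1e-9)
  f <- generate_weather(cfg, years = 30, seed = 2024)
  n_years <- length(f$temp) / 365.25
  expect_lt(abs(mean(f$temp) - 11.5), 0.5)
  annual_p <- sum(f$precip) / n_years
  expect_lt(abs(annual_p - 983), 2 * 247 / sqrt(30))  # 2 se of a 30-yr mean
  # dry-season (Apr-Sep) precipitation share below the wet-season share
  dry <- season_of(series_dates(f$precip))$dry
  expect_lt(sum(f$precip[dry]), sum(f$precip[!dry]))
})

test_that("degenerate weather configurations behave as documented", {
  expect_error(weather_config(monthly_p_wet = rep(0, 12)), "strictly")
  cfg <- weather_config(monthly_p_wet = rep(1e-9, 12))
  f <- generate_weather(cfg, years = 1, seed = 3)
  expect_equal(sum(f$precip), 0)   # (almost surely) no wet days drawn
})

test_that("delta-change identity, presets and inversion", {
  base <- generate_weather(weather_config(), years = 5, seed = 55)
  ident <- apply_delta_change(base, delta_change(rep(0, 12), rep(1, 12)))
  expect_equal(as.numeric(ident$temp), as.numeric(base$temp))
  expect_equal(as.numeric(ident$precip), as.numeric(base$precip))

  # preset temperature offsets are annualised exactly
  d <- delta_preset("rcp45_near")
  expect_equal(mean(d$dt), 1.3)
  pert <- apply_delta_change(base, d)
  expect_equal(mean(pert$temp) - mean(base$temp), 1.3, tolerance = 1e-9)

  # flat-precipitation algebra: factors average to the annual reduction
  flat <- climate_forcing(base$temp,
                          daily_series(rep(2.69, length(base$precip)),
                                       series_start(base$precip), "mm"))
  d85 <- delta_preset("rcp85_far")
  pert85 <- apply_delta_change(flat, d85)
  expect_equal(mean(pert85$precip) / mean(flat$precip), 0.72,
               tolerance = 0.001)
  # summer reduction stronger than winter reduction
  m <- as.integer(format(series_dates(base$precip), "%m"))
  expect_true(max(d85$p_factor[c(6, 7, 8)]) < min(d85$p_factor[c(12, 1, 2)]))

  # inverse profile restores the original series
  inv <- delta_change(-d85$dt, 1 / d85$p_factor)
  back <- apply_delta_change(apply_delta_change(base, d85), inv)
  expect_equal(as.numeric(back$precip), as.numeric(base$precip),
               tolerance = 1e-9)
  expect_equal(as.numeric(back$temp), as.numeric(base$temp),
               tolerance = 1e-9)
})

test_that("truth runs degrade the simulation as configured", {
  f <- toy_forcing(365 + 400)
  ps <- parameter_set()
  rc <- montseny_reference_catchment()
  clean <- generate_truth_run(f, rc, ps, noise_sd = 0, missing_fraction = 0,
                              seed = 1)
  expect_equal(as.numeric(clean$obs), as.numeric(clean$truth$streamflow))

  noisy <- generate_truth_run(f, rc, ps, noise_sd = 0.2,
                              missing_fraction = 0.11, seed = 9)
  n <- length(noisy$obs)
  expect_equal(sum(is.na(noisy$obs)) / n, 0.11, tolerance = 0.01)
  # gaps arrive as a few contiguous blocks, not scattered days
  gaps <- rle(is.na(as.numeric(noisy$obs)))
  expect_lte(sum(gaps$values), 5)
  # multiplicative noise keeps flows non-negative
  expect_true(all(noisy$obs >= 0, na.rm = TRUE))
  # reproducible
  noisy2 <- generate_truth_run(f, rc, ps, noise_sd = 0.2,
                               missing_fraction = 0.11, seed = 9)
  expect_identical(as.numeric(noisy$obs), as.numeric(noisy2$obs))
})

test_that("an 11% gap fraction on a 5-year record emulates ~89% completeness", {
  f <- toy_forcing(365 + 1826)
  tr <- generate_truth_run(f, montseny_reference_catchment(),
                           parameter_set(), missing_fraction = 0.11,
                           seed = 4)
  expect_equal(length(tr$obs), 1826)
  expect_equal(sum(!is.na(tr$obs)), 1826 - round(0.11 * 1826),
               tolerance = 5 / 1626)
  expect_equal(round(100 * completeness(tr$obs)), 89)
})
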