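# analytic impulse response of a discrete linear reservoir with same-day
# outflow: out(t) = (1/tau) (1 - 1/tau)^t for an impulse at t = 0
reservoir_kernel <- function(tau, n) (1 / tau) * (1 - 1 / tau)^(0:(n - 1))

convolve_causal <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (t in seq_len(n)) out[t] <- sum(a[seq_len(t)] * rev(b[seq_len(t)]))
  out
}

test_that("parameter set exposes exactly 28 calibration parameters", {
  flat <- flatten_parameters(parameter_set())
  expect_length(flat, 28)
  expect_true("snow_threshold" %in% names(flat))
  expect_equal(nrow(default_parameter_ranges()), 28)
  expect_identical(sort(rownames(default_parameter_ranges())),
                   sort(names(flat)))
  rt <- flatten_parameters(unflatten_parameters(flat))
  expect_equal(rt, flat)
})

test_that("groundwater-only flow is a geometric recession", {
  # no rain, ET off, storage only in groundwater: V_g(t) = V_g(0)(1-1/tau)^t
  tau <- 5
  ps <- uniform_params(tau_gw = tau, et_rate = 0,
                       initial = c(quick = 0, soil = 0, gw = 10))
  f <- climate_forcing(daily_series(rep(10, 30), "2011-01-01", "degC"),
                       daily_series(rep(0, 30), "2011-01-01", "mm"))
  s <- simulate_streamflow(f, single_unit_catchment(), ps, spinup_days = 0)
  expect_equal(as.numeric(s$streamflow)[1], 2.0)   # 10 / 5
  expect_equal(s$storages$holm_oak$gw[1], 8.0)
  expected_q <- 10 * (1 - 1 / tau)^(0:29) / tau
  expect_equal(as.numeric(s$streamflow), expected_q, tolerance = 1e-12)
})

test_that("zero precipitation and empty storages give zero streamflow", {
  ps <- uniform_params(initial = c(quick = 0, soil = 0, gw = 0))
  f <- climate_forcing(daily_series(rep(15, 50), "2011-01-01", "degC"),
                       daily_series(rep(0, 50), "2011-01-01", "mm"))
  s <- simulate_streamflow(f, montseny_reference_catchment(), ps,
                           spinup_days = 0)
  expect_true(all(as.numeric(s$streamflow) == 0))
})

test_that("soil at field capacity removes the ET limitation", {
  # AET = PET when V_s = field_capacity, for any adjustment exponent
  for (adj in c(0, 1, 2.7)) {
    ps <- uniform_params(et_rate = 0.2, et_threshold = 0, et_adjustment = adj,
                         field_capacity = 150, tau_quick = 1,
                         initial = c(quick = 0, soil = 150, gw = 0))
    f <- climate_forcing(daily_series(10, "2011-01-01", "degC"),
                         daily_series(0, "2011-01-01", "mm"))
    s <- simulate_streamflow(f, single_unit_catchment(), ps, spinup_days = 0)
    expect_equal(as.numeric(s$aet), 0.2 * 10)
  }
})

test_that("increasing the ET adjustment never increases AET below capacity", {
  f <- toy_forcing(200, rain_every = 10, rain_mm = 6)  # soil stays dry
  aet_tot <- vapply(c(0, 0.5, 1, 2, 3), function(adj) {
    ps <- uniform_params(et_adjustment = adj, field_capacity = 300,
                         initial = c(quick = 0, soil = 50, gw = 10))
    sum(simulate_streamflow(f, single_unit_catchment(), ps,
                            spinup_days = 0)$aet)
  }, 0)
  expect_true(all(diff(aet_tot) <= 1e-12))
})

test_that("linear-reservoir cascade impulse response matches convolution", {
  n <- 120
  tau_q <- 2; tau_s <- 3; tau_g <- 10; f_gw <- 0.4; impulse <- 20
  ps <- uniform_params(tau_quick = tau_q, tau_soil = tau_s, tau_gw = tau_g,
                       field_capacity = 1e-12, soil_to_gw = f_gw,
                       et_rate = 0, initial = c(quick = 0, soil = 0, gw = 0))
  prec <- c(impulse, rep(0, n - 1))
  f <- climate_forcing(daily_series(rep(10, n), "2011-01-01", "degC"),
                       daily_series(prec, "2011-01-01", "mm"))
  s <- simulate_streamflow(f, single_unit_catchment(), ps, spinup_days = 0)

  kq <- reservoir_kernel(tau_q, n)
  ks <- reservoir_kernel(tau_s, n)
  kg <- reservoir_kernel(tau_g, n)
  qs <- convolve_causal(kq, ks)                   # quick -> soil, same day
  expected <- impulse *
    ((1 - f_gw) * qs + f_gw * convolve_causal(qs, kg))
  expect_equal(as.numeric(s$streamflow), expected, tolerance = 1e-9)
  # peak lags the rain day in a cascaded response with tau_quick > 1
  expect_gt(which.max(as.numeric(s$streamflow)), 1)
})

test_that("water balance closes for random parameter sets", {
  set.seed(7)
  f <- toy_forcing(730)
  for (i in 1:25) {
    ps <- unflatten_parameters(random_flat_params())
    s <- simulate_streamflow(f, montseny_reference_catchment(), ps,
                             spinup_days = 0)
    expect_lt(max(abs(s$water_balance[, "closure"])), 1e-6)
    expect_true(all(as.numeric(s$streamflow) >= 0))
    expect_false(anyNA(s$streamflow))
  }
})

test_that("identical landscape units collapse to a single unit (mixture degeneracy)", {
  f <- toy_forcing(400)
  ps <- uniform_params(tau_soil = 4, tau_gw = 25)
  for (cov in list(c(0.3, 0.7, 0), c(0.2, 0.3, 0.5))) {
    mixed <- catchment_spec(2, c(holm_oak = cov[1], beech = cov[2],
                                 heathland = cov[3]))
    q_mixed <- simulate_streamflow(f, mixed, ps, spinup_days = 0)$streamflow
    q_single <- simulate_streamflow(f, single_unit_catchment(), ps,
                                    spinup_days = 0)$streamflow
    expect_equal(as.numeric(q_mixed), as.numeric(q_single), tolerance = 1e-12)
  }
})

test_that("snow accumulates below the threshold and melts by degree-days", {
  ps <- uniform_params(melt_rate = 2, et_rate = 0, snow_threshold = 0,
                       field_capacity = 1, tau_soil = 1, soil_to_gw = 0,
                       initial = c(quick = 0, soil = 0, gw = 0))
  temp <- c(-5, -5, 3, 3, 3)
  prec <- c(10, 10, 0, 0, 0)
  f <- climate_forcing(daily_series(temp, "2011-01-01", "degC"),
                       daily_series(prec, "2011-01-01", "mm"))
  s <- simulate_streamflow(f, single_unit_catchment(), ps, spinup_days = 0)
  snow <- s$storages$holm_oak$snowpack
  expect_equal(snow[1:2], c(10, 20))            # accumulation, no melt
  expect_equal(snow[3], 20 - 2 * 3)             # melt = melt_rate * (T - 0)
  # with snow disabled everything is rain and no pack forms
  s2 <- simulate_streamflow(f, single_unit_catchment(), ps,
                            spinup_days = 0, snow = FALSE)
  expect_true(all(s2$storages$holm_oak$snowpack == 0))
  expect_gt(sum(s2$streamflow), sum(s$streamflow))
})

test_that("forcing problems are rejected", {
  expect_error(climate_forcing(
    daily_series(c(1, NA), "2011-01-01", "degC"),
    daily_series(c(0, 0), "2011-01-01", "mm")), "missing")
  expect_error(climate_forcing(
    daily_series(1:3, "2011-01-01", "degC"),
    daily_series(1:4, "2011-01-01", "mm")), "aligned")
  f <- toy_forcing(10)
  expect_error(simulate_streamflow(f, single_unit_catchment(),
                                   parameter_set(), spinup_days = 10),
               "spinup")
})
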