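test_that("day-over-day differences handle values and gaps correctly", {
  q <- daily_series(c(1, 3, 2, 10), "2011-01-01", "L/s")
  qd <- qdiff_series(q)
  expect_equal(as.numeric(qd), c(2, -1, 8))
  expect_equal(series_start(qd), as.Date("2011-01-02"))
  # constant series -> all zeros
  expect_true(all(qdiff_series(
    daily_series(rep(4, 10), "2011-01-01", "L/s")) == 0))
  # both days must be observed
  qg <- daily_series(c(1, NA, 2, 3), "2011-01-01", "L/s")
  expect_equal(as.numeric(qdiff_series(qg)), c(NA, NA, 1))
  # reversal property: qdiff(rev(q)) = -rev(qdiff(q))
  v <- c(0.3, 2, 1.4, 8, 0.1)
  fwd <- as.numeric(qdiff_series(daily_series(v, "2011-01-01", "L/s")))
  bwd <- as.numeric(qdiff_series(daily_series(rev(v), "2011-01-01", "L/s")))
  expect_equal(bwd, -rev(fwd))
})

test_that("a record with k observed runs yields n_obs - k differences", {
  # 20 observed days in 4 runs -> 16 differences
  v <- rep(NA_real_, 30)
  runs <- list(1:6, 9:13, 16:20, 25:28)
  for (r in runs) v[r] <- 1
  q <- daily_series(v, "2011-01-01", "L/s")
  expect_equal(sum(!is.na(qdiff_series(q))),
               sum(!is.na(q)) - length(runs))
})

test_that("percentile threshold interpolates at rank 1 + p(n-1)", {
  expect_equal(percentile_threshold(1:100, 0.99), 99.01)
  expect_equal(percentile_threshold(rep(7, 50), 0.5), 7)
  expect_equal(percentile_threshold(c(1:10, NA, NA), 0.5), 5.5)
  expect_error(percentile_threshold(1:5, 0.99), "at least")
})

test_that("below-threshold day counts and events enumerate correctly", {
  q <- daily_series(c(0.5, 0.2, 0.1, 0.4, 0.3, 0.3), "2011-01-01", "L/s")
  expect_equal(count_days_below(q, 0.33), 4)
  ev <- events_below(q, 0.33)
  expect_equal(ev$duration, c(2, 2))
  expect_equal(ev$start, as.Date(c("2011-01-02", "2011-01-05")))
  # all below -> one event spanning the series
  qa <- daily_series(rep(0.1, 5), "2011-01-01", "L/s")
  expect_equal(events_below(qa, 0.33)$duration, 5)
  # strict comparison: a day exactly at the threshold is not below
  expect_equal(count_days_below(
    daily_series(c(0.33, 0.32), "2011-01-01", "L/s"), 0.33), 1)
})

test_that("a missing day breaks a consecutive-day run", {
  q <- daily_series(c(0.1, 0.1, NA, 0.1, 0.1), "2011-01-01", "L/s")
  ev <- events_below(q, 0.33)
  expect_equal(ev$duration, c(2, 2))
  expect_equal(sum(ev$duration), count_days_below(q, 0.33))
})

test_that("event durations always partition the day count", {
  set.seed(42)
  for (i in 1:30) {
    v <- runif(200, 0, 1)
    v[sample(200, 20)] <- NA
    q <- daily_series(v, "2011-01-01", "L/s")
    thr <- runif(1, 0.1, 0.9)
    expect_equal(sum(events_below(q, thr)$duration),
                 count_days_below(q, thr))
  }
})

test_that("day counts are monotone in the threshold across the sweep", {
  set.seed(3)
  q <- daily_series(rexp(500, 1), "2011-01-01", "L/s")
  sweep <- c(2, 1, 0.5, 0.33, 0.25, 0.2)
  counts <- vapply(sweep, function(t) count_days_below(q, t), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("duration bins encode week/month/quarter boundaries", {
  b <- bin_event_durations(c(1, 6, 7, 30, 31, 90, 91, 200))
  expect_equal(as.integer(b), c(2, 2, 2, 2))
  expect_equal(names(b), c("<7", "7-30", "31-90", ">90"))
})

test_that("single-day spate events count every exceedance independently", {
  qd <- daily_series(c(100, 98, 50, 10), "2011-01-02", "L/s")
  expect_equal(count_single_day_events_above(qd, 97), 2)
  expect_equal(count_single_day_events_above(qd, 200), 0)
  # dry-season restriction by the later day of the difference
  qd2 <- daily_series(c(100, 100), "2011-03-31", "L/s")
  # values dated Mar 31 (wet) and Apr 1 (dry)
  expect_equal(count_single_day_events_above(qd2, 97, dry_only = TRUE), 1)
})

test_that("flow-duration curve uses Weibull positions and is monotone", {
  fdc <- flow_duration_curve(daily_series(c(1, 2, 3), "2011-01-01", "mm/day"))
  expect_equal(fdc$exceedance, c(25, 50, 75))
  expect_equal(fdc$flow, c(3, 2, 1))
  # permutation invariance and monotonicity
  set.seed(9)
  v <- rexp(100)
  f1 <- flow_duration_curve(daily_series(v, "2011-01-01", "mm/day"))
  f2 <- flow_duration_curve(daily_series(sample(v), "2011-01-01", "mm/day"))
  expect_equal(f1, f2)
  expect_true(all(diff(f1$flow) <= 0))
  # fraction of curve below a threshold ~ days_below / n
  thr <- median(v)
  expect_equal(mean(f1$flow < thr),
               count_days_below(daily_series(v, "2011-01-01", "mm/day"),
                                thr) / length(v))
})

test_that("threshold robustness correlates scenario day counts", {
  mk <- function(scale) daily_series(scale * rep(c(0.1, 0.3, 0.6, 1.5, 2.5),
                                                 20), "2011-01-01", "L/s")
  flows <- list(a = mk(1), b = mk(0.5), c = mk(2), d = mk(1.3))
  tr <- threshold_robustness(flows)
  expect_equal(tr$threshold, c(2, 1, 0.5, 0.25, 0.2))
  expect_true(all(tr$correlation <= 1 & tr$correlation >= -1, na.rm = TRUE))
  # identical count vectors -> r = 1 (use thresholds giving equal counts)
  flows_id <- list(a = mk(1), b = mk(1), c = mk(1))
  expect_error(threshold_robustness(flows_id[1:2]), "at least 3")
  # anti-ordered toy vectors give r = -1 through the correlation core
  expect_equal(cor(c(1, 2, 3), c(3, 2, 1)), -1)
})

test_that("best lag finds a constructed 1-day response and breaks ties low", {
  set.seed(11)
  p <- c(rexp(199), 0)
  q1 <- c(0, head(p, -1))            # Q(t) = P(t-1)
  pp <- daily_series(p, "2011-01-01", "mm")
  expect_equal(as.integer(best_lag(pp,
    daily_series(q1, "2011-01-01", "mm/day"))), 1L)
  expect_equal(as.integer(best_lag(pp,
    daily_series(p, "2011-01-01", "mm/day"))), 0L)
  # noisy linear response recovers lag 1 in most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    p <- rexp(400)
    q <- 0.7 * c(0, head(p, -1)) + rnorm(400, 0, 0.1 * mean(p))
    as.integer(best_lag(daily_series(p, "2011-01-01", "mm"),
                        daily_series(q, "2011-01-01", "mm/day")))
  }, 0L)
  expect_gte(mean(hits == 1L), 0.95)
})

test_that("event summary aggregates all habitat statistics coherently", {
  set.seed(5)
  v <- rexp(730, 3)
  q <- daily_series(v, "2011-01-01", "mm/day")
  thr <- threshold_spec(area_km2 = 2)
  es <- event_summary(q, thr)
  expect_equal(sum(es$event_durations), es$days_below)
  expect_lte(es$events_below, es$days_below)
  expect_equal(es$annual_q, mean(v) * 365.25)
  expect_equal(sum(es$seasonal_days_below), es$days_below)
  expect_equal(sum(es$duration_bins), es$events_below)
})
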