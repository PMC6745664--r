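#' Day-over-day flow difference
#'
#' `qdiff(t) = q(t) - q(t-1)`, the flow-increase statistic whose upper
#' percentiles define spate-event thresholds (sudden flow rises drive
#' catastrophic downstream drift of stream fauna). A difference is defined
#' only where both days are observed, so every boundary of a gap in the
#' record removes one value: a record with k maximal runs of observed days
#' yields `n_obs - k` differences.
#'
#' @param q streamflow `daily_series` (typically L/s).
#' @return `daily_series` of length `length(q) - 1`, starting one day
#'   after `q`, same units.
#' @examples
#' qdiff_series(daily_series(c(1, 3, 2, 10), "2011-01-01", "L/s"))
#' @export
qdiff_series <- function(q) {
  stopifnot(inherits(q, "daily_series"))
  if (length(q) < 2L) stop("need at least 2 days to difference")
  v <- as.numeric(unclass(q))
  daily_series(v[-1L] - v[-length(v)], series_start(q) + 1L, series_units(q))
}

#' Empirical percentile threshold
#'
#' Linear interpolation between order statistics at rank `1 + p (n - 1)`
#' (the default quantile definition of [stats::quantile()], type 7).
#'
#' @param values numeric vector; missing values dropped.
#' @param p percentile in (0, 1), default 0.99.
#' @param min_n minimum number of non-missing values required.
#' @return the percentile value.
#' @examples
#' percentile_threshold(1:100)  # 99.01
#' @export
percentile_threshold <- function(values, p = 0.99, min_n = 10) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < min_n)
    stop(sprintf("need at least %d non-missing values", min_n))
  unname(quantile(values, p, type = 7))
}

#' Low-flow day and event statistics
#'
#' `count_days_below()` counts observed days with flow strictly below the
#' threshold. `events_below()` returns the maximal runs of consecutive
#' below-threshold days as a data.frame of start dates and durations; a
#' missing day terminates a run (an unobserved day cannot attest
#' continuity). Durations always partition the day count exactly.
#'
#' @param q streamflow `daily_series` in the same units as `threshold`.
#' @param threshold flow threshold (strict `<` comparison).
#' @return `count_days_below()`: integer count. `events_below()`:
#'   data.frame with columns `start` (Date) and `duration` (days).
#' @examples
#' q <- daily_series(c(0.5, 0.2, 0.1, 0.4, 0.3, 0.3), "2011-01-01", "L/s")
#' count_days_below(q, 0.33)  # 4
#' events_below(q, 0.33)      # two events of 2 days
#' @export
count_days_below <- function(q, threshold) {
  stopifnot(inherits(q, "daily_series"))
  sum(as.numeric(q) < threshold, na.rm = TRUE)
}

#' @rdname count_days_below
#' @export
events_below <- function(q, threshold) {
  stopifnot(inherits(q, "daily_series"))
  below <- as.numeric(q) < threshold
  below[is.na(below)] <- FALSE   # missing day breaks any run
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = series_dates(q)[starts[keep]],
             duration = r$lengths[keep])
}

#' Bin low-flow event durations
#'
#' Histogram bins for event-duration summaries: shorter than a week, a
#' week to a month, a month to three months, longer than three months.
#'
#' @param durations integer day counts (e.g. from [events_below()]).
#' @return named integer vector over bins `<7`, `7-30`, `31-90`, `>90`.
#' @export
bin_event_durations <- function(durations) {
  bins <- cut(durations, c(0, 6, 30, 90, Inf),
              labels = c("<7", "7-30", "31-90", ">90"))
  table(bins)
}

#' Single-day spate events above a flow-increase threshold
#'
#' Counts non-missing day-over-day flow increases strictly above the
#' threshold. Every exceedance is one event, independent of whether the
#' next day also exceeds. The dry-season variant keeps only differences
#' whose later day falls in April-September (the rise manifests on that
#' day).
#'
#' @param qdiff `daily_series` from [qdiff_series()].
#' @param threshold spate threshold in the units of `qdiff`.
#' @param dry_only restrict to dry-season differences.
#' @return integer count.
#' @examples
#' qd <- daily_series(c(100, 98, 50, 10), "2011-01-02", "L/s")
#' count_single_day_events_above(qd, 97)  # 2
#' @export
count_single_day_events_above <- function(qdiff, threshold,
                                          dry_only = FALSE) {
  stopifnot(inherits(qdiff, "daily_series"))
  v <- as.numeric(qdiff)
  if (dry_only) v[!season_of(series_dates(qdiff))$dry] <- NA
  sum(v > threshold, na.rm = TRUE)
}

#' Flow-duration curve
#'
#' Flows sorted descending against Weibull plotting positions
#' `100 i / (n + 1)`: the percentage of time each flow is equalled or
#' exceeded.
#'
#' @param q streamflow `daily_series` (missing days dropped).
#' @return data.frame with columns `exceedance` (percent, increasing) and
#'   `flow` (non-increasing), one row per observed day.
#' @export
flow_duration_curve <- function(q) {
  stopifnot(inherits(q, "daily_series"))
  v <- sort(as.numeric(q)[!is.na(q)], decreasing = TRUE)
  if (!length(v)) stop("no non-missing values")
  data.frame(exceedance = 100 * seq_along(v) / (length(v) + 1), flow = v)
}

#' Low-flow threshold robustness across scenarios
#'
#' Checks whether scenario conclusions depend on the exact choice of the
#' low-flow threshold: for each alternative threshold, the day counts per
#' scenario are correlated (Pearson) against the counts under the
#' reference threshold. Near-1 correlations mean the scenario ranking is
#' threshold-robust.
#'
#' @param scenario_flows named list of streamflow `daily_series`, one per
#'   scenario, all in the units of the thresholds.
#' @param reference_threshold the adopted low-flow threshold (default
#'   0.33 L/s).
#' @param alternatives alternative thresholds (default 2, 1, 0.5, 0.25,
#'   0.2 L/s).
#' @return data.frame with columns `threshold` and `correlation`
#'   (`NA` where a count vector is constant).
#' @export
threshold_robustness <- function(scenario_flows, reference_threshold = 0.33,
                                 alternatives = c(2, 1, 0.5, 0.25, 0.2)) {
  if (length(scenario_flows) < 3L) stop("need at least 3 scenarios")
  counts <- function(thr) vapply(scenario_flows, function(s)
    as.numeric(count_days_below(s, thr)), numeric(1))
  ref <- counts(reference_threshold)
  corr <- vapply(alternatives, function(thr) {
    alt <- counts(thr)
    if (var(ref) == 0 || var(alt) == 0) return(NA_real_)
    cor(ref, alt)
  }, 0)
  data.frame(threshold = alternatives, correlation = corr)
}

#' Precipitation-to-streamflow lag
#'
#' The lag k in days maximising the Pearson correlation between `P(t)` and
#' `Q(t + k)` over pairwise-complete days; ties break to the smallest lag.
#' A flashy Mediterranean headwater typically shows a 1-day lag.
#'
#' @param p precipitation `daily_series`.
#' @param q streamflow `daily_series`, aligned with `p`.
#' @param max_lag largest lag considered (days, >= 1).
#' @return best lag in days; attribute `correlations` holds the full
#'   lag-correlation vector.
#' @export
best_lag <- function(p, q, max_lag = 10) {
  check_aligned(p, q)
  if (max_lag < 1) stop("'max_lag' must be >= 1")
  pv <- as.numeric(p); qv <- as.numeric(q); n <- length(pv)
  cors <- vapply(0:max_lag, function(k) {
    a <- pv[seq_len(n - k)]
    b <- qv[seq_len(n - k) + k]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L || var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, 0)
  if (all(is.na(cors))) stop("insufficient overlap at every lag")
  best <- which.max(cors) - 1L   # which.max picks the first (smallest) tie
  structure(best, correlations = stats::setNames(cors, 0:max_lag))
}

#' Summarise habitat-relevant flow events of one simulated record
#'
#' The per-scenario summary row: days and events below the low-flow
#' threshold, single-day spate events above the whole-year and dry-season
#' thresholds, mean annual flow, and the seasonal distribution of low-flow
#' days.
#'
#' @param q streamflow `daily_series` in mm/day.
#' @param thresholds a [threshold_spec()] (thresholds in L/s; the area it
#'   carries does the unit conversion).
#' @return object of class `event_summary`: list with `days_below`,
#'   `events_below`, `event_durations`, `duration_bins`,
#'   `events_above_all`, `events_above_dry`, `annual_q` (mm/year),
#'   `seasonal_days_below`, `n_days`.
#' @export
event_summary <- function(q, thresholds) {
  stopifnot(inherits(q, "daily_series"), inherits(thresholds, "threshold_spec"))
  if (series_units(q) != "mm/day") stop("event_summary expects q in mm/day")
  q_ls <- mmday_to_ls(q, thresholds$area_km2)
  qd <- qdiff_series(q_ls)
  ev <- events_below(q_ls, thresholds$q_low)
  below_days <- !is.na(q_ls) & as.numeric(q_ls) < thresholds$q_low
  seas <- season_of(series_dates(q_ls))$season
  structure(list(
    days_below = count_days_below(q_ls, thresholds$q_low),
    events_below = nrow(ev),
    event_durations = ev$duration,
    duration_bins = bin_event_durations(ev$duration),
    events_above_all = count_single_day_events_above(qd, thresholds$qdiff_all),
    events_above_dry = count_single_day_events_above(qd, thresholds$qdiff_dry,
                                                     dry_only = TRUE),
    annual_q = mean(as.numeric(q), na.rm = TRUE) * 365.25,
    seasonal_days_below = tapply(below_days, seas, sum),
    n_days = sum(!is.na(q))),
    class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf(paste0("<event_summary> %d observed days\n",
                     "  below q_low: %d days in %d events; ",
                     "spates: %d (all-year), %d (dry season)\n",
                     "  annual flow %.0f mm/year\n"),
              x$n_days, x$days_below, x$events_below,
              x$events_above_all, x$events_above_dry, x$annual_q))
  invisible(x)
}
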