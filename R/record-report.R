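#' Threshold statistics of an observed streamflow record
#'
#' The observation-record analysis chain in one call: record completeness,
#' day-over-day differences with gap-boundary exclusion, the
#' 99th-percentile spate thresholds for the whole year and the dry
#' season, counts of days below the low-flow threshold and of single-day
#' events above each spate threshold, and (when precipitation is
#' supplied) the precipitation-to-streamflow lag. Run it on any local
#' copy of a gauged record (e.g. converted to the `date,value` CSV layout
#' with [read_daily_csv()]) to validate the percentile and gap-handling
#' conventions against published values.
#'
#' @param q observed streamflow `daily_series`; mm/day series are
#'   converted using `area_km2`.
#' @param area_km2 catchment area (km2) for unit conversion.
#' @param q_low low-flow threshold in L/s.
#' @param percentile spate-threshold percentile (default 0.99).
#' @param p optional precipitation `daily_series` aligned with `q`.
#' @param max_lag largest lag tried for the cross-correlation.
#' @return object of class `record_report`: list with `n_days`,
#'   `n_observed`, `completeness`, `n_qdiff`, `qdiff_all_threshold`,
#'   `qdiff_dry_threshold` (L/s), `days_below_qlow`, `events_above_all`,
#'   `events_above_dry`, and `lag_days` (NA without precipitation).
#' @export
record_report <- function(q, area_km2 = 2, q_low = 0.33, percentile = 0.99,
                          p = NULL, max_lag = 10) {
  stopifnot(inherits(q, "daily_series"))
  q_ls <- switch(series_units(q),
                 "mm/day" = mmday_to_ls(q, area_km2),
                 "L/s" = q,
                 stop("streamflow units must be mm/day or L/s"))
  qd <- qdiff_series(q_ls)
  dry <- season_of(series_dates(qd))$dry
  qd_dry <- as.numeric(qd)[dry]
  thr_all <- percentile_threshold(as.numeric(qd), percentile)
  thr_dry <- percentile_threshold(qd_dry, percentile)
  lag <- NA_integer_
  if (!is.null(p)) lag <- as.integer(best_lag(p, q, max_lag = max_lag))
  structure(list(
    n_days = length(q_ls),
    n_observed = sum(!is.na(q_ls)),
    completeness = completeness(q_ls),
    n_qdiff = sum(!is.na(qd)),
    n_qdiff_dry = sum(!is.na(qd_dry)),
    qdiff_all_threshold = thr_all,
    qdiff_dry_threshold = thr_dry,
    days_below_qlow = count_days_below(q_ls, q_low),
    events_above_all = count_single_day_events_above(qd, thr_all),
    events_above_dry = count_single_day_events_above(qd, thr_dry,
                                                     dry_only = TRUE),
    q_low = q_low, percentile = percentile, lag_days = lag),
    class = "record_report")
}

#' @export
print.record_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<record_report> %d of %d days observed (%.0f%% complete)\n",
    "  q_diff: N = %d (whole year), N = %d (dry season)\n",
    "  99th-percentile spate thresholds: %.3g L/s (all), %.3g L/s (dry)\n",
    "  days below q_low = %.3g L/s: %d; single-day spates: %d (all), %d (dry)\n"),
    x$n_observed, x$n_days, 100 * x$completeness,
    x$n_qdiff, x$n_qdiff_dry,
    x$qdiff_all_threshold, x$qdiff_dry_threshold,
    x$q_low, x$days_below_qlow, x$events_above_all, x$events_above_dry))
  if (!is.na(x$lag_days))
    cat(sprintf("  precipitation-to-streamflow lag: %d day(s)\n", x$lag_days))
  invisible(x)
}
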