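pairwise_complete <- function(obs, sim) {
  if (inherits(obs, "daily_series") && inherits(sim, "daily_series"))
    check_aligned(obs, sim)
  obs <- as.numeric(obs); sim <- as.numeric(sim)
  if (length(obs) != length(sim)) stop("series are not aligned")
  ok <- !is.na(obs) & !is.na(sim)
  list(obs = obs[ok], sim = sim[ok])
}

#' Streamflow goodness-of-fit metrics
#'
#' The four hard calibration criteria. All metrics are computed on
#' pairwise-complete days: days where the observation is missing are
#' dropped from both series, so the ~11% gaps of a typical pressure-sensor
#' record never bias a metric.
#'
#' * `nash_sutcliffe()` — efficiency `1 - SSE / SS_obs`; 1 is a perfect
#'   fit, 0 no better than the observed mean; emphasises high flows.
#' * `log_nash_sutcliffe()` — the same on `log(x + offset)`; emphasises
#'   low flows. The offset (default 0.01 mm/day) admits zero flows.
#' * `relative_volume_difference()` — percent bias of cumulative simulated
#'   versus observed volume.
#' * `variance_ratio()` — observed over simulated variance; automated
#'   calibration tends to produce under-dispersed simulations, so values
#'   near 1 are wanted.
#'
#' @param obs,sim aligned `daily_series` (or plain numeric vectors) of
#'   streamflow in the same units.
#' @return a single number (RVD in percent).
#' @examples
#' nash_sutcliffe(c(1, 2, 3), c(1.5, 2, 2.5))   # 0.75
#' relative_volume_difference(c(1, 2, 3), c(1, 2, 3.3))  # +5
#' @export
nash_sutcliffe <- function(obs, sim) {
  pc <- pairwise_complete(obs, sim)
  if (length(pc$obs) < 2L) stop("need at least 2 pairwise-complete days")
  ss_obs <- sum((pc$obs - mean(pc$obs))^2)
  if (ss_obs == 0) stop("Nash-Sutcliffe undefined for constant observations")
  1 - sum((pc$obs - pc$sim)^2) / ss_obs
}

#' @rdname nash_sutcliffe
#' @param offset positive value added before taking logs (same units as
#'   the series).
#' @export
log_nash_sutcliffe <- function(obs, sim, offset = 0.01) {
  if (offset < 0) stop("'offset' must be >= 0")
  pc <- pairwise_complete(obs, sim)
  if (any(pc$obs + offset <= 0) || any(pc$sim + offset <= 0))
    stop("log transform needs all values + offset > 0")
  nash_sutcliffe(log(pc$obs + offset), log(pc$sim + offset))
}

#' @rdname nash_sutcliffe
#' @export
relative_volume_difference <- function(obs, sim) {
  pc <- pairwise_complete(obs, sim)
  if (sum(pc$obs) <= 0) stop("observed volume must be positive")
  100 * (sum(pc$sim) - sum(pc$obs)) / sum(pc$obs)
}

#' @rdname nash_sutcliffe
#' @export
variance_ratio <- function(obs, sim) {
  pc <- pairwise_complete(obs, sim)
  if (length(pc$obs) < 2L) stop("need at least 2 pairwise-complete days")
  vo <- var(pc$obs); vs <- var(pc$sim)
  if (vs == 0) stop("variance ratio undefined for constant simulation")
  if (vo == 0) stop("variance ratio undefined for constant observations")
  vo / vs
}

#' Ecological threshold specification
#'
#' Thresholds defining the habitat-relevant flow events for a
#' stream-dwelling amphibian: the low-flow threshold `q_low` below which
#' downstream reaches lose surface flow, and the day-over-day
#' flow-increase (spate) thresholds `qdiff_all` / `qdiff_dry`, defined as
#' the 99th percentile of observed consecutive-day flow differences over
#' the whole year and the dry season (April-September) respectively.
#' Defaults are the observed values for the Montseny reference catchment.
#'
#' @param q_low low-flow threshold in L/s (default 0.33).
#' @param qdiff_all whole-year spate threshold in L/s (default 97).
#' @param qdiff_dry dry-season spate threshold in L/s (default 42).
#' @param area_km2 catchment area used to convert mm/day series to L/s.
#' @param percentile percentile defining spate thresholds when recomputed
#'   from data.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(q_low = 0.33, qdiff_all = 97, qdiff_dry = 42,
                           area_km2 = 2, percentile = 0.99) {
  if (any(c(q_low, qdiff_all, qdiff_dry) <= 0))
    stop("thresholds must be positive")
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0,1)")
  structure(list(q_low = q_low, qdiff_all = qdiff_all,
                 qdiff_dry = qdiff_dry, area_km2 = area_km2,
                 percentile = percentile),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "<threshold_spec> q_low %.3g L/s; qdiff_all %.3g L/s; qdiff_dry %.3g L/s (area %.3g km2)\n",
    x$q_low, x$qdiff_all, x$qdiff_dry, x$area_km2))
  invisible(x)
}

#' Soft calibration penalties: event-count mismatches
#'
#' Beyond the four hard metrics, calibration aims to reproduce the
#' observed counts of habitat-relevant threshold events: days below
#' `q_low`, and single-day events above the whole-year and dry-season
#' spate thresholds. Returns the absolute count differences.
#'
#' @param obs,sim aligned streamflow `daily_series` in mm/day.
#' @param thresholds a [threshold_spec()].
#' @return named numeric: `q_low_days`, `qdiff_all_events`,
#'   `qdiff_dry_events`.
#' @export
soft_penalties <- function(obs, sim, thresholds) {
  stopifnot(inherits(thresholds, "threshold_spec"))
  co <- event_counts_ls(obs, thresholds)
  cs <- event_counts_ls(sim, thresholds)
  abs(co - cs)
}

event_counts_ls <- function(q, thresholds) {
  q_ls <- mmday_to_ls(q, thresholds$area_km2)
  qd <- qdiff_series(q_ls)
  c(q_low_days = count_days_below(q_ls, thresholds$q_low),
    qdiff_all_events = count_single_day_events_above(qd, thresholds$qdiff_all),
    qdiff_dry_events = count_single_day_events_above(qd, thresholds$qdiff_dry,
                                                     dry_only = TRUE))
}

#' Composite calibration objective
#'
#' Single scalar total order over candidate parameter sets (higher is
#' better):
#' `NS + logNS - w_rvd * |RVD|/100 - w_var * |1 - VAR| - sum(w_soft * soft/norm)`
#' where soft penalties are normalised by the observed event counts
#' (floored at 1). A perfect fit with zero penalties scores 2.
#'
#' @param metrics named list/vector with `ns`, `log_ns`, `rvd`,
#'   `var_ratio` and optionally `soft` (named absolute count differences)
#'   plus `soft_norm` (observed counts used for normalisation).
#' @param w_rvd,w_var,w_soft weights (defaults 1, 1, 0.5).
#' @return scalar objective.
#' @export
composite_objective <- function(metrics, w_rvd = 1, w_var = 1, w_soft = 0.5) {
  val <- metrics$ns + metrics$log_ns -
    w_rvd * abs(metrics$rvd) / 100 -
    w_var * abs(1 - metrics$var_ratio)
  if (!is.null(metrics$soft)) {
    norm <- pmax(1, metrics$soft_norm[names(metrics$soft)])
    val <- val - sum(w_soft * metrics$soft / norm)
  }
  val
}
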