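MONTH_DAYS <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Configuration for the synthetic Mediterranean weather generator
#'
#' Parameters of a seeded daily weather generator emulating the subhumid
#' Mediterranean climate of the Montseny massif: mild winters, wet springs
#' and autumns, dry summers; mean annual temperature about 11.5 degC and
#' mean annual precipitation about 983 mm. Temperature is a seasonal
#' sinusoid plus AR(1) noise; precipitation is a two-state first-order
#' occurrence chain with monthly wet-day probabilities and persistence,
#' and gamma-distributed wet-day amounts. Monthly gamma scales are derived
#' analytically from the monthly precipitation weights so that the
#' expected annual total equals `annual_p` by construction. Defaults are
#' documented choices, not values fitted to any record.
#'
#' @param mean_annual_t mean annual air temperature (degC).
#' @param t_amplitude seasonal half-range of daily mean temperature
#'   (degC); peak in late July.
#' @param t_ar1 lag-1 autocorrelation of temperature anomalies.
#' @param t_noise_sd stationary standard deviation of temperature
#'   anomalies (degC).
#' @param annual_p expected annual precipitation (mm).
#' @param monthly_weights relative monthly precipitation totals (length
#'   12, rescaled internally).
#' @param monthly_p_wet monthly wet-day probabilities (length 12).
#' @param wet_persistence extra wet-after-wet persistence r in \[0, 1):
#'   P(wet|wet) = p + r(1-p), P(wet|dry) = p(1-r), which keeps the
#'   stationary wet-day probability at p.
#' @param gamma_shape shape of the wet-day amount distribution.
#' @return object of class `weather_config`.
#' @export
weather_config <- function(mean_annual_t = 11.5, t_amplitude = 7.5,
                           t_ar1 = 0.7, t_noise_sd = 1.6,
                           annual_p = 983,
                           monthly_weights = c(62, 55, 75, 92, 90, 55,
                                               28, 42, 82, 115, 95, 75),
                           monthly_p_wet = c(0.22, 0.20, 0.25, 0.30, 0.30,
                                             0.20, 0.10, 0.12, 0.22, 0.30,
                                             0.26, 0.22),
                           wet_persistence = 0.25, gamma_shape = 0.7) {
  stopifnot(length(monthly_weights) == 12, length(monthly_p_wet) == 12)
  if (any(monthly_p_wet <= 0 | monthly_p_wet >= 1))
    stop("monthly_p_wet must lie strictly in (0, 1)")
  if (wet_persistence < 0 || wet_persistence >= 1)
    stop("wet_persistence must lie in [0, 1)")
  if (gamma_shape <= 0 || annual_p <= 0 || any(monthly_weights < 0))
    stop("gamma_shape, annual_p and monthly_weights must be positive")
  if (t_ar1 < 0 || t_ar1 >= 1) stop("t_ar1 must lie in [0, 1)")
  target_m <- annual_p * monthly_weights / sum(monthly_weights)
  # E[month total] = ndays * p_wet * shape * scale  =>  solve for scale
  gamma_scale <- target_m / (MONTH_DAYS * monthly_p_wet * gamma_shape)
  structure(list(mean_annual_t = mean_annual_t, t_amplitude = t_amplitude,
                 t_ar1 = t_ar1, t_noise_sd = t_noise_sd,
                 annual_p = annual_p, monthly_p_wet = monthly_p_wet,
                 wet_persistence = wet_persistence,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "weather_config")
}

#' Expected annual precipitation implied by a weather configuration
#'
#' Analytic expectation `sum over months of ndays p_wet shape scale`; by
#' construction equal to the configured `annual_p`.
#'
#' @param config a [weather_config()].
#' @return expected annual precipitation (mm).
#' @export
expected_annual_precipitation <- function(config) {
  sum(MONTH_DAYS * config$monthly_p_wet * config$gamma_shape *
        config$gamma_scale)
}

#' Generate synthetic daily Mediterranean weather
#'
#' @param config a [weather_config()].
#' @param years number of calendar years (>= 1).
#' @param seed integer RNG seed; identical seeds give identical series.
#' @param start first day (default "2001-01-01").
#' @return a [climate_forcing()].
#' @examples
#' f <- generate_weather(weather_config(), years = 2, seed = 42)
#' mean(f$temp)
#' @export
generate_weather <- function(config, years, seed, start = "2001-01-01") {
  stopifnot(inherits(config, "weather_config"))
  if (years < 1) stop("'years' must be >= 1")
  start <- as.Date(start)
  end <- seq(start, by = paste(years, "years"), length.out = 2)[2] - 1
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  m <- as.integer(format(dates, "%m"))
  doy <- as.integer(format(dates, "%j"))
  set.seed(as.integer(seed))

  # temperature: sinusoid peaking late July + stationary AR(1) anomalies
  seasonal <- config$mean_annual_t +
    config$t_amplitude * cos(2 * pi * (doy - 205) / 365.25)
  innov_sd <- config$t_noise_sd * sqrt(1 - config$t_ar1^2)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, config$t_noise_sd)
  eps <- rnorm(n, 0, innov_sd)
  for (t in 2:n) e[t] <- config$t_ar1 * e[t - 1] + eps[t]
  temp <- seasonal + e

  # precipitation occurrence: monthly two-state chain; amounts: gamma
  p <- config$monthly_p_wet[m]
  p_ww <- p + config$wet_persistence * (1 - p)
  p_wd <- p * (1 - config$wet_persistence)
  u <- runif(n)
  wet <- logical(n)
  wet[1] <- u[1] < p[1]
  for (t in 2:n) wet[t] <- u[t] < (if (wet[t - 1]) p_ww[t] else p_wd[t])
  prec <- numeric(n)
  nw <- sum(wet)
  if (nw > 0)
    prec[wet] <- rgamma(nw, shape = config$gamma_shape,
                        scale = config$gamma_scale[m[wet]])

  climate_forcing(daily_series(temp, start, "degC"),
                  daily_series(prec, start, "mm"))
}

#' Monthly delta-change perturbation of a forcing series
#'
#' The delta-change method generates future forcing from a baseline:
#' temperature is shifted by a monthly offset and precipitation scaled by
#' a monthly factor. `delta_change()` builds an explicit perturbation;
#' `delta_preset()` returns profiles whose annual means match downscaled
#' Mediterranean projections for the Montseny area — warming of +1.3
#' (near future, both pathways), +1.8 (far future, moderate pathway
#' RCP4.5) and +3.9 degC (far future, high pathway RCP8.5), with annual
#' precipitation reductions of 11, 16, 17 and 28% respectively, the
#' reduction relatively stronger in the already dry summer months and
#' weakest in winter. Monthly profiles beyond those annual means are
#' approximate shapes, not downscaled values.
#'
#' @param dt_monthly 12 monthly temperature offsets (degC).
#' @param p_factor_monthly 12 monthly precipitation factors (>= 0).
#' @return object of class `delta_change`.
#' @export
delta_change <- function(dt_monthly, p_factor_monthly) {
  stopifnot(length(dt_monthly) == 12, length(p_factor_monthly) == 12)
  if (any(p_factor_monthly < 0)) stop("precipitation factors must be >= 0")
  structure(list(dt = as.numeric(dt_monthly),
                 p_factor = as.numeric(p_factor_monthly)),
            class = "delta_change")
}

#' @rdname delta_change
#' @param name one of `"rcp45_near"`, `"rcp85_near"`, `"rcp45_far"`,
#'   `"rcp85_far"`.
#' @export
delta_preset <- function(name = c("rcp45_near", "rcp85_near", "rcp45_far",
                                  "rcp85_far")) {
  name <- match.arg(name)
  ann <- switch(name,
    rcp45_near = c(dt = 1.3, dp = 0.11),
    rcp85_near = c(dt = 1.3, dp = 0.16),
    rcp45_far  = c(dt = 1.8, dp = 0.17),
    rcp85_far  = c(dt = 3.9, dp = 0.28))
  # seasonal shape of the relative precipitation reduction:
  # weakest in winter (DJF), strongest in summer (JJA); day-weighted mean 1
  shape <- c(0.5, 0.5, 0.9, 0.9, 0.9, 1.7, 1.7, 1.7, 1.0, 1.0, 1.0, 0.5)
  w <- MONTH_DAYS / sum(MONTH_DAYS)
  shape <- shape / sum(w * shape)
  delta_change(rep(ann[["dt"]], 12), 1 - ann[["dp"]] * shape)
}

#' @rdname delta_change
#' @param forcing a [climate_forcing()] to perturb.
#' @param delta a `delta_change`.
#' @export
apply_delta_change <- function(forcing, delta) {
  stopifnot(inherits(forcing, "climate_forcing"),
            inherits(delta, "delta_change"))
  m <- as.integer(format(series_dates(forcing$temp), "%m"))
  start <- series_start(forcing$temp)
  climate_forcing(
    daily_series(as.numeric(forcing$temp) + delta$dt[m], start, "degC"),
    daily_series(as.numeric(forcing$precip) * delta$p_factor[m], start, "mm"))
}

#' Synthetic truth run: model-generated observations with noise and gaps
#'
#' Parameter-recovery harness: simulates streamflow from known "true"
#' parameters, then degrades it into a pseudo-observed record with
#' multiplicative lognormal noise (median 1, so flows stay positive and
#' errors scale with magnitude) and a fraction of days masked as missing
#' in a few contiguous blocks, mimicking instrument outages.
#'
#' @param forcing a [climate_forcing()] covering spin-up + window.
#' @param catchment a [catchment_spec()].
#' @param true_params the generating [parameter_set()].
#' @param noise_sd standard deviation of log-noise (0 = exact truth).
#' @param missing_fraction fraction of days masked, in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @param n_blocks number of contiguous outage blocks.
#' @param spinup_days,snow passed to [simulate_streamflow()].
#' @return list with `obs` (degraded `daily_series`, mm/day) and `truth`
#'   (the clean `simulation_result`).
#' @export
generate_truth_run <- function(forcing, catchment, true_params,
                               noise_sd = 0, missing_fraction = 0,
                               seed = 1, n_blocks = 5,
                               spinup_days = 365, snow = TRUE) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (missing_fraction < 0 || missing_fraction > 0.5)
    stop("'missing_fraction' must lie in [0, 0.5]")
  truth <- simulate_streamflow(forcing, catchment, true_params,
                               spinup_days = spinup_days, snow = snow)
  q <- as.numeric(truth$streamflow)
  n <- length(q)
  set.seed(as.integer(seed))
  obs <- if (noise_sd > 0) q * exp(rnorm(n, 0, noise_sd)) else q

  if (missing_fraction > 0) {
    total <- round(missing_fraction * n)
    n_blocks <- max(1L, min(n_blocks, total))
    sizes <- diff(round(seq(0, total, length.out = n_blocks + 1)))
    # place blocks by splitting the observed days into random gaps
    free <- n - total
    cuts <- sort(runif(n_blocks))
    gaps <- diff(round(c(0, cuts, 1) * free))
    pos <- 0L
    for (b in seq_len(n_blocks)) {
      pos <- pos + gaps[b]
      if (sizes[b] > 0) obs[(pos + 1):(pos + sizes[b])] <- NA
      pos <- pos + sizes[b]
    }
  }
  list(obs = daily_series(obs, series_start(truth$streamflow), "mm/day"),
       truth = truth)
}
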