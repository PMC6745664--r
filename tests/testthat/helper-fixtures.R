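# deterministic toy forcing: seasonal temperature, periodic rain pulses
toy_forcing <- function(days, start = "2011-01-01",
                        temp_mean = 11.5, rain_every = 7, rain_mm = 18) {
  t_idx <- seq_len(days)
  temp <- temp_mean + 7.5 * cos(2 * pi * (t_idx - 205) / 365.25)
  prec <- ifelse(t_idx %% rain_every == 0, rain_mm, 0)
  climate_forcing(daily_series(temp, start, "degC"),
                  daily_series(prec, start, "mm"))
}

# one identical parameterization for all three landscape units
uniform_params <- function(..., snow_threshold = 0,
                           initial = c(quick = 0, soil = 100, gw = 50)) {
  u <- unit_parameters(...)
  parameter_set(holm_oak = u, beech = u, heathland = u,
                snow_threshold = snow_threshold, initial = initial)
}

single_unit_catchment <- function(area = 2) {
  catchment_spec(area, c(holm_oak = 1, beech = 0, heathland = 0))
}

# draw one random flat parameter vector within ranges
random_flat_params <- function(ranges = default_parameter_ranges()) {
  v <- runif(nrow(ranges), ranges$low, ranges$high)
  names(v) <- rownames(ranges)
  v
}
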