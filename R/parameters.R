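UNIT_NAMES <- c("holm_oak", "beech", "heathland")

# per-landscape-unit tunables; snow_threshold is shared globally,
# giving 3 x 9 + 1 = 28 calibration parameters
UNIT_PARAM_NAMES <- c("tau_quick", "tau_soil", "tau_gw", "field_capacity",
                      "soil_to_gw", "et_rate", "et_threshold",
                      "et_adjustment", "melt_rate")

#' Parameters of one landscape unit
#'
#' Each landscape unit is a cascade of three buckets: a quick box routing
#' precipitation to the soil, a shallow soil layer producing fast runoff,
#' and a groundwater layer regulating base flow. Outflows are linear in
#' storage with residence times in days; actual evapotranspiration is a
#' degree-day demand limited by soil wetness through a power-law
#' adjustment exponent (larger exponent = stronger limitation when the
#' soil is below field capacity).
#'
#' @param tau_quick,tau_soil,tau_gw residence times in days, each >= 1
#'   (guarantees per-step outflow never exceeds storage).
#' @param field_capacity soil moisture threshold (mm) above which the soil
#'   drains; > 0.
#' @param soil_to_gw fraction of soil drainage recharging groundwater, in
#'   \[0, 1\]; the remainder reaches the stream directly.
#' @param et_rate degree-day evapotranspiration rate (mm per degC per day),
#'   >= 0.
#' @param et_threshold air temperature (degC) above which evapotranspiration
#'   demand starts.
#' @param et_adjustment dimensionless exponent >= 0 limiting
#'   evapotranspiration under dry soil conditions.
#' @param melt_rate degree-day snowmelt rate (mm per degC per day), >= 0.
#' @return named numeric vector of class `unit_parameters`.
#' @export
unit_parameters <- function(tau_quick = 1, tau_soil = 3, tau_gw = 30,
                            field_capacity = 150, soil_to_gw = 0.5,
                            et_rate = 0.2, et_threshold = 0,
                            et_adjustment = 1, melt_rate = 3) {
  p <- c(tau_quick = tau_quick, tau_soil = tau_soil, tau_gw = tau_gw,
         field_capacity = field_capacity, soil_to_gw = soil_to_gw,
         et_rate = et_rate, et_threshold = et_threshold,
         et_adjustment = et_adjustment, melt_rate = melt_rate)
  validate_unit_parameters(p)
  structure(p, class = "unit_parameters")
}

validate_unit_parameters <- function(p) {
  if (!all(UNIT_PARAM_NAMES %in% names(p)))
    stop("missing unit parameters: ",
         paste(setdiff(UNIT_PARAM_NAMES, names(p)), collapse = ", "))
  if (any(!is.finite(p[UNIT_PARAM_NAMES])))
    stop("unit parameters must be finite")
  if (p[["tau_quick"]] < 1 || p[["tau_soil"]] < 1 || p[["tau_gw"]] < 1)
    stop("residence times must be >= 1 day")
  if (p[["field_capacity"]] <= 0) stop("field_capacity must be > 0")
  if (p[["soil_to_gw"]] < 0 || p[["soil_to_gw"]] > 1)
    stop("soil_to_gw must lie in [0, 1]")
  if (p[["et_rate"]] < 0 || p[["et_adjustment"]] < 0 || p[["melt_rate"]] < 0)
    stop("et_rate, et_adjustment and melt_rate must be >= 0")
  invisible(p)
}

#' Full model parameterization
#'
#' One [unit_parameters()] set per landscape unit plus the global snow
#' temperature threshold and the initial bucket storages. 28 parameters in
#' total are exposed to calibration: nine per unit and one shared snow
#' threshold.
#'
#' @param holm_oak,beech,heathland `unit_parameters` for each landscape
#'   unit.
#' @param snow_threshold air temperature (degC) below which precipitation
#'   accumulates as snow; shared by all units.
#' @param initial named numeric vector of initial storages in mm
#'   (`quick`, `soil`, `gw`), each >= 0, applied to every unit.
#' @return object of class `parameter_set`.
#' @examples
#' ps <- parameter_set()
#' length(flatten_parameters(ps))  # 28
#' @export
parameter_set <- function(holm_oak = unit_parameters(),
                          beech = unit_parameters(),
                          heathland = unit_parameters(),
                          snow_threshold = 0,
                          initial = c(quick = 0, soil = 100, gw = 50)) {
  units <- list(holm_oak = holm_oak, beech = beech, heathland = heathland)
  for (u in units) validate_unit_parameters(u)
  if (!is.finite(snow_threshold)) stop("snow_threshold must be finite")
  req <- c("quick", "soil", "gw")
  if (!all(req %in% names(initial)) || any(initial[req] < 0))
    stop("'initial' must give non-negative quick, soil and gw storages")
  structure(list(units = units, snow_threshold = snow_threshold,
                 initial = initial[req]),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> 28 parameters (9 per landscape unit + global snow threshold)\n")
  m <- do.call(rbind, lapply(x$units, unclass))
  print(round(m, 4))
  cat(sprintf("snow_threshold: %.3g degC; initial storages (mm): %s\n",
              x$snow_threshold,
              paste(sprintf("%s=%.3g", names(x$initial), x$initial),
                    collapse = ", ")))
  invisible(x)
}

#' Flatten / rebuild a parameter set
#'
#' The flat form is a named numeric vector with keys `<unit>.<parameter>`
#' plus `snow_threshold` — the representation sampled by Monte-Carlo
#' calibration and tested by the sensitivity screen.
#'
#' @param params a `parameter_set`.
#' @return `flatten_parameters()`: named numeric vector of length 28.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  out <- unlist(lapply(UNIT_NAMES, function(u) {
    v <- unclass(params$units[[u]])[UNIT_PARAM_NAMES]
    names(v) <- paste(u, UNIT_PARAM_NAMES, sep = ".")
    v
  }))
  c(out, snow_threshold = params$snow_threshold)
}

#' @rdname flatten_parameters
#' @param flat named numeric vector as produced by `flatten_parameters()`.
#' @param initial initial storages passed through to [parameter_set()].
#' @export
unflatten_parameters <- function(flat,
                                 initial = c(quick = 0, soil = 100, gw = 50)) {
  units <- lapply(UNIT_NAMES, function(u) {
    keys <- paste(u, UNIT_PARAM_NAMES, sep = ".")
    if (!all(keys %in% names(flat)))
      stop("flat vector is missing parameters for unit ", u)
    p <- flat[keys]
    names(p) <- UNIT_PARAM_NAMES
    structure(p, class = "unit_parameters")
  })
  names(units) <- UNIT_NAMES
  parameter_set(holm_oak = units$holm_oak, beech = units$beech,
                heathland = units$heathland,
                snow_threshold = flat[["snow_threshold"]],
                initial = initial)
}

#' Default Monte-Carlo sampling ranges
#'
#' Initial uniform sampling ranges for all 28 parameters, one row per
#' parameter with columns `low` and `high`. These play the role of the
#' expert-judged credible ranges that precede automated calibration; edit
#' the returned data.frame (or supply your own) to encode manual
#' calibration knowledge.
#'
#' @return data.frame with rownames = flat parameter names.
#' @export
default_parameter_ranges <- function() {
  per_unit <- rbind(
    tau_quick      = c(1, 5),
    tau_soil       = c(1, 30),
    tau_gw         = c(5, 150),
    field_capacity = c(50, 400),
    soil_to_gw     = c(0.1, 0.9),
    et_rate        = c(0.05, 0.4),
    et_threshold   = c(-2, 5),
    et_adjustment  = c(0, 3),
    melt_rate      = c(1, 6))
  rows <- do.call(rbind, lapply(UNIT_NAMES, function(u) {
    m <- per_unit
    rownames(m) <- paste(u, rownames(per_unit), sep = ".")
    m
  }))
  rows <- rbind(rows, snow_threshold = c(-2, 2))
  out <- as.data.frame(rows)
  names(out) <- c("low", "high")
  out
}

#' Read / write flat parameter and range files
#'
#' Plain-text key-value files: `<unit>.<parameter> = value` for parameter
#' files and `<unit>.<parameter> = low, high` for range files. Blank lines
#' and `#` comments are ignored.
#'
#' @param path file path.
#' @return `read_parameter_file()`: a `parameter_set`;
#'   `read_ranges_file()`: a ranges data.frame as in
#'   [default_parameter_ranges()].
#' @export
read_parameter_file <- function(path) {
  kv <- read_key_values(path)
  unflatten_parameters(vapply(kv, function(v) as.numeric(v[1]), 0))
}

#' @rdname read_parameter_file
#' @param params a `parameter_set` to write.
#' @export
write_parameter_file <- function(params, path) {
  flat <- flatten_parameters(params)
  writeLines(sprintf("%s = %.10g", names(flat), flat), path)
  invisible(path)
}

#' @rdname read_parameter_file
#' @export
read_ranges_file <- function(path) {
  kv <- read_key_values(path)
  m <- t(vapply(kv, function(v) {
    if (length(v) != 2L) stop("range lines need exactly 'low, high'")
    as.numeric(v)
  }, numeric(2)))
  out <- data.frame(low = m[, 1], high = m[, 2], row.names = names(kv))
  if (any(out$low >= out$high)) stop("every range needs low < high")
  out
}

read_key_values <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("'%s': cannot parse line %d", path, bad[1L]))
  vals <- lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]]))
  names(vals) <- trimws(vapply(parts, `[`, "", 1L))
  vals
}
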