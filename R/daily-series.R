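#' Calendar-contiguous daily time series
#'
#' A `daily_series` is a numeric vector with one slot per calendar day,
#' starting at `start`. Missing observations are explicit `NA`s, never
#' skipped dates, so arithmetic on day offsets is always safe. Every series
#' carries a units tag which is consulted before any operation that mixes
#' two series or compares a series against a threshold.
#'
#' @param values numeric vector, one element per day (`NA` = missing).
#' @param start first calendar day (`Date` or ISO-8601 string).
#' @param units one of `"mm/day"`, `"L/s"`, `"degC"`, `"mm"`.
#' @return object of class `daily_series`.
#' @examples
#' q <- daily_series(c(1.2, NA, 0.8), "2011-01-01", "mm/day")
#' series_dates(q)
#' completeness(q)
#' @export
daily_series <- function(values, start, units) {
  units <- match.arg(units, c("mm/day", "L/s", "degC", "mm"))
  start <- as.Date(start)
  if (is.na(start)) stop("'start' is not a valid date")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a daily series needs at least one day")
  structure(values, start = start, units = units, class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  d <- series_dates(x)
  cat(sprintf("<daily_series> %d days, %s .. %s [%s], %d missing\n",
              length(x), format(d[1]), format(d[length(x)]),
              series_units(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname daily_series
#' @param x a `daily_series`.
#' @export
series_dates <- function(x) {
  stopifnot(inherits(x, "daily_series"))
  attr(x, "start") + seq_along(x) - 1L
}

#' @rdname daily_series
#' @export
series_units <- function(x) attr(x, "units")

#' @rdname daily_series
#' @export
series_start <- function(x) attr(x, "start")

#' @export
as.data.frame.daily_series <- function(x, ...) {
  data.frame(date = series_dates(x), value = as.numeric(unclass(x)))
}

#' Fraction of non-missing days
#'
#' @param x a `daily_series`.
#' @return fraction in \[0, 1\].
#' @export
completeness <- function(x) {
  stopifnot(inherits(x, "daily_series"))
  mean(!is.na(x))
}

# keep attributes through subsetting by day index
#' @export
`[.daily_series` <- function(x, i, ...) {
  i <- if (is.logical(i)) which(i) else as.integer(i)
  if (any(diff(i) != 1L)) {
    # non-contiguous selection loses the calendar; return plain numeric
    return(unclass(x)[i])
  }
  daily_series(unclass(x)[i], attr(x, "start") + i[1L] - 1L, attr(x, "units"))
}

check_aligned <- function(a, b) {
  stopifnot(inherits(a, "daily_series"), inherits(b, "daily_series"))
  if (series_start(a) != series_start(b) || length(a) != length(b))
    stop("series are not aligned (different start date or length)")
  invisible(TRUE)
}

#' Convert streamflow between areal (mm/day) and volumetric (L/s) units
#'
#' Areally normalised streamflow in mm/day over a catchment of `area` km2
#' corresponds to `q * area * 1e6 / 86400` litres per second.
#'
#' @param q non-negative streamflow value(s), or a `daily_series`.
#' @param area catchment area in km2, > 0.
#' @return converted value(s); a `daily_series` keeps its calendar and gets
#'   the new units tag.
#' @examples
#' mmday_to_ls(1, 2)   # 23.148... L/s
#' ls_to_mmday(0.33, 2)
#' @export
mmday_to_ls <- function(q, area) {
  conv_check(q, area, "mm/day")
  out <- q * area * (1e6 / 86400)
  conv_retag(out, q, "L/s")
}

#' @rdname mmday_to_ls
#' @export
ls_to_mmday <- function(q, area) {
  conv_check(q, area, "L/s")
  out <- q / (area * (1e6 / 86400))
  conv_retag(out, q, "mm/day")
}

conv_check <- function(q, area, expected_units) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("'area' must be a single positive number (km2)")
  if (any(q < 0, na.rm = TRUE)) stop("streamflow must be non-negative")
  if (inherits(q, "daily_series") && series_units(q) != expected_units)
    stop(sprintf("series units are '%s', expected '%s'",
                 series_units(q), expected_units))
  invisible(TRUE)
}

conv_retag <- function(out, template, units) {
  if (inherits(template, "daily_series")) {
    daily_series(unclass(out), series_start(template), units)
  } else out
}

#' Hydrological and meteorological season of a date
#'
#' The dry season is April 1 to September 30 and the wet season October 1
#' to March 31, the split under which dry-season spate thresholds are
#' computed. Meteorological seasons are DJF / MAM / JJA / SON.
#'
#' @param date `Date` vector (or coercible).
#' @return data.frame with columns `dry` (logical, TRUE = dry season) and
#'   `season` (factor: winter, spring, summer, autumn).
#' @examples
#' season_of(as.Date(c("2011-04-15", "2011-10-01", "2011-12-31")))
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("invalid date")
  m <- as.integer(format(date, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  data.frame(dry = m >= 4L & m <= 9L,
             season = factor(season, levels = c("winter", "spring",
                                                "summer", "autumn")))
}

#' Read / write daily series CSV
#'
#' The on-disk layout is a two-column CSV `date,value` with ISO-8601 dates
#' and an empty value field for a missing day. Dates need not be contiguous
#' in the file: gaps between listed dates are filled with missing markers on
#' reading, so the returned series is always calendar-contiguous.
#'
#' @param path file path.
#' @param units units tag for the series (see [daily_series()]).
#' @param quiet suppress the missing-day count message.
#' @return a `daily_series`.
#' @export
read_daily_csv <- function(path, units, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "numeric"))
  if (!identical(names(df)[1:2], c("date", "value")))
    stop(sprintf("'%s': expected header 'date,value'", path))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1L]
    stop(sprintf("'%s': unparseable date on data row %d ('%s')",
                 path, bad, df$date[bad]))
  }
  if (anyDuplicated(dates)) {
    dup <- which(duplicated(dates))[1L]
    stop(sprintf("'%s': duplicate date on data row %d ('%s')",
                 path, dup, df$date[dup]))
  }
  o <- order(dates)
  dates <- dates[o]
  vals <- df$value[o]
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  out <- rep(NA_real_, length(full))
  out[match(dates, full)] <- vals
  if (!quiet)
    message(sprintf("read %d days (%d missing) from %s",
                    length(full), sum(is.na(out)), path))
  daily_series(out, full[1L], units)
}

#' One-shot conversion of a spreadsheet record to the canonical CSV layout
#'
#' Deposited gauged records often arrive as spreadsheets. This converts one
#' sheet (a date column plus a value column) to the `date,value` CSV layout
#' that the rest of the pipeline reads; the pipeline proper never touches
#' spreadsheets. Requires the readxl package.
#'
#' @param path xlsx file.
#' @param out_csv destination CSV path.
#' @param sheet sheet name or index.
#' @param date_col,value_col column names or indices in the sheet.
#' @return `out_csv`, invisibly.
#' @export
xlsx_to_daily_csv <- function(path, out_csv, sheet = 1, date_col = 1,
                              value_col = 2) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("xlsx conversion needs the 'readxl' package")
  df <- readxl::read_excel(path, sheet = sheet)
  out <- data.frame(date = format(as.Date(df[[date_col]]), "%Y-%m-%d"),
                    value = as.numeric(df[[value_col]]))
  out <- out[!is.na(out$date), ]
  write.csv(out, out_csv, row.names = FALSE, quote = FALSE, na = "")
  invisible(out_csv)
}

#' @rdname read_daily_csv
#' @param x a `daily_series` to write.
#' @export
write_daily_csv <- function(x, path) {
  stopifnot(inherits(x, "daily_series"))
  df <- as.data.frame(x)
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
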