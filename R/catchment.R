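#' Catchment descriptor
#'
#' Area and landscape-cover fractions of the simulated catchment. The three
#' named covers are the landscape units of the runoff model: holm oak
#' forest, beech forest and heathland. Fractions must sum to one.
#'
#' @param area_km2 catchment area in km2, > 0.
#' @param cover_fractions named numeric vector with elements `holm_oak`,
#'   `beech`, `heathland`, each in \[0, 1\], summing to 1 within 1e-9.
#' @return object of class `catchment_spec`.
#' @examples
#' montseny_reference_catchment()
#' @export
catchment_spec <- function(area_km2, cover_fractions) {
  if (!is.numeric(area_km2) || length(area_km2) != 1L || area_km2 <= 0)
    stop("'area_km2' must be a single positive number")
  req <- c("holm_oak", "beech", "heathland")
  if (!all(req %in% names(cover_fractions)))
    stop("cover_fractions must name holm_oak, beech and heathland")
  f <- as.numeric(cover_fractions[req])
  names(f) <- req
  if (any(f < 0 | f > 1)) stop("cover fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop(sprintf("cover fractions sum to %.12f, not 1", sum(f)))
  structure(list(area_km2 = area_km2, cover_fractions = f),
            class = "catchment_spec")
}

#' @export
print.catchment_spec <- function(x, ...) {
  cat(sprintf("<catchment_spec> area %.3g km2; covers: %s\n", x$area_km2,
              paste(sprintf("%s %.1f%%", names(x$cover_fractions),
                            100 * x$cover_fractions), collapse = ", ")))
  invisible(x)
}

#' The 2-km2 Montseny reference catchment
#'
#' Present-day cover: holm oak 52.2%, beech 15.1%, heathland 32.7%.
#' @return a `catchment_spec`.
#' @export
montseny_reference_catchment <- function() {
  catchment_spec(2, c(holm_oak = 0.522, beech = 0.151, heathland = 0.327))
}

#' Vegetation-cover change scenarios
#'
#' Transforms the cover fractions of a catchment according to one of four
#' vegetation scenarios describing the ongoing altitudinal expansion of
#' holm oak forest:
#' \describe{
#'   \item{i}{vegetation as present (identity);}
#'   \item{ii}{holm oak takes over 50% of the beech area and beech in turn
#'     takes over 50% of the heathland area;}
#'   \item{iii}{holm oak takes over 50% of the beech area, heathland
#'     unchanged;}
#'   \item{iv}{holm oak covers the whole catchment.}
#' }
#' Total area is conserved exactly in every scenario.
#'
#' @param catchment a `catchment_spec`.
#' @param scenario one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @return a new `catchment_spec` with transformed cover fractions.
#' @examples
#' rc <- montseny_reference_catchment()
#' apply_vegetation_scenario(rc, "ii")$cover_fractions * 100
#' @export
apply_vegetation_scenario <- function(catchment, scenario) {
  stopifnot(inherits(catchment, "catchment_spec"))
  scenario <- as.character(scenario)
  f <- catchment$cover_fractions
  h <- f[["holm_oak"]]; b <- f[["beech"]]; he <- f[["heathland"]]
  new <- switch(scenario,
    i   = c(h, b, he),
    ii  = c(h + b / 2, b / 2 + he / 2, he / 2),
    iii = c(h + b / 2, b / 2, he),
    iv  = c(1, 0, 0),
    stop(sprintf("unknown vegetation scenario '%s'", scenario)))
  names(new) <- c("holm_oak", "beech", "heathland")
  # re-normalise the float residue so downstream sum-to-1 checks stay exact
  new <- new / sum(new)
  catchment_spec(catchment$area_km2, new)
}

#' Round half away from zero
#'
#' Decimal reporting helper matching the usual table convention (0.5 rounds
#' up), unlike [round()]'s round-half-even. A tiny epsilon absorbs float
#' representation error on exact halves.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
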