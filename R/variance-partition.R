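#' Main-effects ANOVA variance partition of scenario outcomes
#'
#' Decomposes the variation of an outcome across the balanced 2 x 2 x 4
#' scenario matrix (period x climate x vegetation, one value per cell)
#' into main-effect contributions as fractions of the total sum of
#' squares: `SS_factor = sum over levels of n_level (level mean - grand
#' mean)^2`, fraction = `100 SS_factor / SS_total`. No interaction terms
#' are fitted — in a single-replicate saturated design the residual would
#' be identically zero and the partition uninformative; under main
#' effects only, the residual absorbs all interaction structure. The
#' "model" share is the sum of the three factor shares.
#'
#' @param values numeric outcomes, one per scenario cell (length 16 for
#'   the full design).
#' @param period,climate,vegetation factor level labels per value.
#' @return object of class `variance_partition`: named fractions (percent)
#'   `period`, `climate`, `vegetation`, `model`, `residual`, plus the
#'   underlying sums of squares as attribute `ss`.
#' @examples
#' tab <- montseny_scenario_table()
#' fut <- tab[tab$period != "reference", ]
#' variance_partition(fut$qlow_days, fut$period, fut$climate, fut$vegetation)
#' @export
variance_partition <- function(values, period, climate, vegetation) {
  values <- as.numeric(values)
  f <- list(period = factor(period), climate = factor(climate),
            vegetation = factor(vegetation))
  if (!all(lengths(f) == length(values)))
    stop("factor vectors must match 'values' in length")
  cells <- interaction(f$period, f$climate, f$vegetation, drop = FALSE)
  counts <- table(cells)
  if (any(counts == 0))
    stop("incomplete design; missing cells: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (length(unique(counts)) != 1L)
    stop("design is unbalanced")

  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss <- vapply(f, function(fac) {
    lv <- split(values, fac)
    sum(vapply(lv, function(v) length(v) * (mean(v) - gm)^2, 0))
  }, 0)
  if (ss_total == 0) {
    warning("all outcomes identical: zero total variation")
    frac <- c(ss * 0, model = 0, residual = 0)
  } else {
    frac <- 100 * ss / ss_total
    frac <- c(frac, model = sum(frac), residual = 100 - sum(frac))
  }
  structure(frac, ss = c(ss, total = ss_total),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition> percent of total sum of squares\n")
  v <- unclass(x)
  # integer percent, one decimal below 1 (table reporting convention)
  shown <- ifelse(abs(v) < 1 & v != 0, sprintf("%.1f", round_half_up(v, 1)),
                  sprintf("%d", as.integer(round_half_up(v, 0))))
  print(stats::setNames(shown, names(v)), quote = FALSE)
  invisible(x)
}
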