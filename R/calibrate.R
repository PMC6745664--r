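#' Monte-Carlo calibration of the bucket model
#'
#' The fitting function of the package. Candidate parameter sets are drawn
#' uniformly within per-parameter ranges, simulated, and scored with the
#' composite objective combining four hard metrics (Nash-Sutcliffe, log
#' Nash-Sutcliffe, relative volume difference, variance ratio) and,
#' optionally, soft event-count criteria. The search runs in iterations:
#' within each, `runs` candidates are sampled and the best kept; between
#' iterations the sampling ranges shrink to the envelope of the current
#' elite (top 5% of all samples so far), inflated by 10% and clipped to
#' the initial ranges. The result holds one best set per iteration — the
#' elite ensemble on which parameter-sensitivity screening operates — and
#' the single global best.
#'
#' A candidate whose simulation fails is scored `-Inf` and recorded; the
#' calibration never aborts. The whole procedure is reproducible from
#' `seed`.
#'
#' @param obs observed streamflow `daily_series` in mm/day, aligned with
#'   the post-spin-up part of `forcing` (missing days allowed; metrics use
#'   pairwise-complete days).
#' @param forcing a [climate_forcing()] covering spin-up + observation
#'   window.
#' @param catchment a [catchment_spec()].
#' @param ranges data.frame of initial sampling ranges as returned by
#'   [default_parameter_ranges()].
#' @param iterations number of refinement iterations (default 100).
#' @param runs candidate draws per iteration (default 1000).
#' @param seed integer RNG seed.
#' @param thresholds optional [threshold_spec()]; when supplied the soft
#'   event-count penalties enter the objective.
#' @param spinup_days spin-up days prepended in `forcing`.
#' @param weights list of objective weights `w_rvd`, `w_var`, `w_soft`.
#' @param initial initial storages (mm) for every candidate.
#' @param snow enable the snow routine.
#' @return object of class `bucket_calibration`; see
#'   [coef.bucket_calibration()], [predict.bucket_calibration()],
#'   [residuals.bucket_calibration()], [parameter_sensitivity()].
#' @seealso [simulate_streamflow()] for the forward model.
#' @export
mc_calibrate <- function(obs, forcing, catchment,
                         ranges = default_parameter_ranges(),
                         iterations = 100, runs = 1000, seed = 1,
                         thresholds = NULL, spinup_days = 365,
                         weights = list(w_rvd = 1, w_var = 1, w_soft = 0.5),
                         initial = c(quick = 0, soil = 100, gw = 50),
                         snow = TRUE) {
  stopifnot(inherits(obs, "daily_series"))
  if (any(ranges$low >= ranges$high)) stop("every range needs low < high")
  n_expected <- length(forcing$temp) - spinup_days
  if (length(obs) != n_expected)
    stop(sprintf("obs has %d days but forcing minus spin-up has %d",
                 length(obs), n_expected))
  if (iterations < 1 || runs < 1) stop("iterations and runs must be >= 1")

  soft_norm <- NULL
  if (!is.null(thresholds)) soft_norm <- event_counts_ls(obs, thresholds)

  par_names <- rownames(ranges)
  initial_ranges <- ranges
  cur <- ranges
  set.seed(as.integer(seed))

  score_one <- function(theta) {
    ps <- try(unflatten_parameters(theta, initial = initial), silent = TRUE)
    if (inherits(ps, "try-error")) return(NULL)
    sim <- try(simulate_streamflow(forcing, catchment, ps,
                                   spinup_days = spinup_days, snow = snow),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(NULL)
    q <- sim$streamflow
    m <- list(ns = try(nash_sutcliffe(obs, q), silent = TRUE),
              log_ns = try(log_nash_sutcliffe(obs, q), silent = TRUE),
              rvd = try(relative_volume_difference(obs, q), silent = TRUE),
              var_ratio = try(variance_ratio(obs, q), silent = TRUE))
    if (any(vapply(m, inherits, TRUE, "try-error"))) return(NULL)
    if (!is.null(thresholds)) {
      m$soft <- soft_penalties(obs, q, thresholds)
      m$soft_norm <- soft_norm
    }
    m$objective <- composite_objective(m, weights$w_rvd, weights$w_var,
                                       weights$w_soft)
    m
  }

  elite_k <- max(1L, ceiling(0.05 * runs))
  iter_best <- vector("list", iterations)
  elite_theta <- NULL   # running elite across iterations
  elite_obj <- NULL
  n_failed <- 0L

  for (it in seq_len(iterations)) {
    theta_m <- matrix(runif(runs * nrow(cur), cur$low, cur$high),
                      ncol = runs)   # column = candidate; recycling by row
    rownames(theta_m) <- par_names
    obj <- rep(-Inf, runs)
    best_in_iter <- NULL
    for (r in seq_len(runs)) {
      m <- score_one(theta_m[, r])
      if (is.null(m)) { n_failed <- n_failed + 1L; next }
      obj[r] <- m$objective
      if (is.null(best_in_iter) || m$objective > best_in_iter$objective)
        best_in_iter <- c(list(theta = theta_m[, r], iteration = it), m)
    }
    if (is.null(best_in_iter))
      stop(sprintf("every candidate failed in iteration %d", it))
    iter_best[[it]] <- best_in_iter

    # refine ranges toward the running elite (top 5% of all samples so far)
    keep <- is.finite(obj)
    elite_theta <- cbind(elite_theta, theta_m[, keep, drop = FALSE])
    elite_obj <- c(elite_obj, obj[keep])
    top <- order(elite_obj, decreasing = TRUE)[
      seq_len(min(length(elite_obj), elite_k * it))]
    elite_theta <- elite_theta[, top, drop = FALSE]
    elite_obj <- elite_obj[top]
    lo <- apply(elite_theta, 1, min)
    hi <- apply(elite_theta, 1, max)
    mid <- (lo + hi) / 2; half <- (hi - lo) / 2 * 1.1
    cur <- data.frame(low = pmax(initial_ranges$low, mid - half),
                      high = pmin(initial_ranges$high, mid + half),
                      row.names = par_names)
    degenerate <- cur$low >= cur$high
    cur$low[degenerate] <- initial_ranges$low[degenerate]
    cur$high[degenerate] <- initial_ranges$high[degenerate]
  }

  objs <- vapply(iter_best, `[[`, 0, "objective")
  ord <- order(objs, decreasing = TRUE)
  top_sets <- do.call(rbind, lapply(iter_best[ord], function(b) {
    row <- as.data.frame(t(b$theta))
    row$iteration <- b$iteration
    row$ns <- b$ns; row$log_ns <- b$log_ns; row$rvd <- b$rvd
    row$var_ratio <- b$var_ratio; row$objective <- b$objective
    row
  }))
  best <- iter_best[[ord[1L]]]

  structure(list(
    best_params = unflatten_parameters(best$theta, initial = initial),
    best_metrics = best[c("ns", "log_ns", "rvd", "var_ratio", "objective")],
    best_soft = best$soft,
    top_sets = top_sets,
    initial_ranges = initial_ranges,
    final_ranges = cur,
    iterations = iterations, runs = runs, seed = seed,
    n_failed = n_failed,
    obs = obs, forcing = forcing, catchment = catchment,
    thresholds = thresholds, spinup_days = spinup_days, snow = snow,
    weights = weights, initial = initial,
    call = match.call()),
    class = "bucket_calibration")
}

#' @export
print.bucket_calibration <- function(x, ...) {
  m <- x$best_metrics
  cat(sprintf(paste0("<bucket_calibration> %d iterations x %d runs (seed %s)\n",
                     "  best: NS %.3f, logNS %.3f, RVD %+.1f%%, VAR %.3f, ",
                     "objective %.3f\n"),
              x$iterations, x$runs, format(x$seed),
              m$ns, m$log_ns, m$rvd, m$var_ratio, m$objective))
  if (!is.null(x$best_soft))
    cat("  soft penalties (|count diff|):",
        paste(sprintf("%s=%d", names(x$best_soft),
                      as.integer(x$best_soft)), collapse = ", "), "\n")
  if (x$n_failed > 0)
    cat(sprintf("  %d failed candidate simulations scored -Inf\n", x$n_failed))
  invisible(x)
}

#' Methods for calibrated bucket models
#'
#' `coef()` returns the flat named vector of the 28 best-fit parameters.
#' `predict()` simulates streamflow from the best set, by default on the
#' calibration forcing. `residuals()` gives observed minus simulated flow
#' on the calibration window (NA on missing days). `summary()` adds
#' elite-ensemble parameter spreads; `plot()` overlays simulated on
#' observed flow.
#'
#' @param object,x a `bucket_calibration`.
#' @param forcing optional alternative [climate_forcing()].
#' @param catchment optional alternative [catchment_spec()].
#' @param spinup_days spin-up override for prediction.
#' @param ... unused.
#' @return see individual method descriptions.
#' @export
coef.bucket_calibration <- function(object, ...) {
  flatten_parameters(object$best_params)
}

#' @rdname coef.bucket_calibration
#' @export
predict.bucket_calibration <- function(object, forcing = NULL,
                                       catchment = NULL,
                                       spinup_days = NULL, ...) {
  simulate_streamflow(forcing %||% object$forcing,
                      catchment %||% object$catchment,
                      object$best_params,
                      spinup_days = spinup_days %||% object$spinup_days,
                      snow = object$snow)$streamflow
}

#' @rdname coef.bucket_calibration
#' @export
residuals.bucket_calibration <- function(object, ...) {
  sim <- predict(object)
  daily_series(as.numeric(object$obs) - as.numeric(sim),
               series_start(sim), series_units(sim))
}

#' @rdname coef.bucket_calibration
#' @export
summary.bucket_calibration <- function(object, ...) {
  flat_cols <- rownames(object$initial_ranges)
  elite <- object$top_sets[, flat_cols, drop = FALSE]
  spread <- data.frame(best = coef(object)[flat_cols],
                       elite_min = apply(elite, 2, min),
                       elite_max = apply(elite, 2, max),
                       initial_low = object$initial_ranges$low,
                       initial_high = object$initial_ranges$high)
  out <- list(fit = object, spread = spread)
  class(out) <- "summary.bucket_calibration"
  out
}

#' @export
print.summary.bucket_calibration <- function(x, ...) {
  print(x$fit)
  cat("\nParameter spread (best set and elite ensemble envelope):\n")
  print(round(x$spread, 4))
  invisible(x)
}

#' @rdname coef.bucket_calibration
#' @export
plot.bucket_calibration <- function(x, ...) {
  sim <- predict(x)
  d <- series_dates(sim)
  ylim <- range(c(as.numeric(sim), as.numeric(x$obs)), na.rm = TRUE)
  plot(d, as.numeric(x$obs), type = "l", col = "grey30",
       xlab = "", ylab = "streamflow (mm/day)", ylim = ylim, ...)
  lines(d, as.numeric(sim), col = "steelblue")
  legend("topright", c("observed", "simulated"), col = c("grey30",
         "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
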