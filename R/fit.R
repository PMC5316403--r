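# Constrained sigmoid fitting. The model is the two-constraint curve
#   V(c) = Top / (1 + 10^(log10 c - log10 EC50)) = Top * EC50 / (EC50 + c),
# i.e. a log-concentration sigmoid with lower plateau fixed at 0 and Hill
# coefficient fixed at -1. Only (Top, log10 EC50) are free; Top can be fixed
# by option. For fixed log10 EC50 the optimal Top has a closed form, so the
# fit profiles Top out and minimizes a one-dimensional function of
# log10 EC50 by a deterministic dense-start search plus local refinement.

#' Fitting options
#'
#' @param fix_top Fix the upper plateau at this value (e.g. 100) instead of
#'   estimating it; `NULL` (default) leaves Top free.
#' @param top_max Upper bound for a free Top, in percent.
#' @param no_fit_viability_pct "No decrease in viability" floor: a series
#'   whose mean viability at its highest tested concentration stays above
#'   this value is called `no_fit`.
#' @param bound_decades How many decades beyond the tested concentration
#'   range the log10 EC50 search extends on each side.
#' @param grid_step Spacing (log10 units) of the deterministic start grid.
#' @return Named list of options for [fit_series()].
#' @export
fit_options <- function(fix_top = NULL, top_max = 150,
                        no_fit_viability_pct = 80,
                        bound_decades = 2, grid_step = 0.05) {
  list(fix_top = fix_top, top_max = top_max,
       no_fit_viability_pct = no_fit_viability_pct,
       bound_decades = bound_decades, grid_step = grid_step)
}

# Profiled residual sum of squares at a vector of candidate log10 EC50s.
# Returns the clamped optimal Top and the RSS for each candidate.
profile_rss <- function(log_ec50, conc, viab, options) {
  w <- 1 / (1 + outer(conc, 10^log_ec50, "/"))    # n x G weights
  if (!is.null(options$fix_top)) {
    top <- rep(options$fix_top, length(log_ec50))
  } else {
    a <- colSums(w * w)
    b <- colSums(viab * w)
    top <- pmin(pmax(b / a, 1e-6), options$top_max)
  }
  resid2 <- sum(viab^2) - 2 * top * colSums(viab * w) +
    top^2 * colSums(w * w)
  list(rss = pmax(resid2, 0), top = top)
}

#' Fit the constrained sigmoid to one dilution series
#'
#' Minimizes the sum of squared residuals of
#' `V(c) = Top * EC50 / (EC50 + c)` over `(Top, log10 EC50)` (or over
#' `log10 EC50` alone when `fix_top` is set). Technical replicates enter as
#' individual residuals. After fitting, the no-fit rule ([no_fit_rule()]) is
#' applied to set `status`.
#'
#' @param concentration_um Positive concentrations (µM), one per point.
#' @param viability_pct Percent-of-vehicle viabilities, same length.
#' @param options See [fit_options()].
#' @return One-row tibble: `log10_ec50`, `ec50_um`, `top`, `rss`,
#'   `n_points`, `df`, `converged`, `status` (`"fit"` or `"no_fit"`).
#' @export
#' @examples
#' cc <- rep(c(3, 5, 10, 30, 50, 100, 300), each = 3)
#' v <- 100 * 50 / (50 + cc)
#' fit_series(cc, v)
fit_series <- function(concentration_um, viability_pct,
                       options = fit_options()) {
  conc <- as.numeric(concentration_um)
  viab <- as.numeric(viability_pct)
  stopifnot(length(conc) == length(viab))
  if (any(!is.finite(conc)) || any(conc <= 0) || any(!is.finite(viab))) {
    stop("fit_series requires finite viabilities at positive concentrations",
         call. = FALSE)
  }
  if (length(unique(conc)) < 5L) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  n <- length(viab)
  n_free <- if (is.null(options$fix_top)) 2L else 1L
  lo <- log10(min(conc)) - options$bound_decades
  hi <- log10(max(conc)) + options$bound_decades

  grid <- seq(lo, hi, by = options$grid_step)
  prof <- profile_rss(grid, conc, viab, options)
  best <- which.min(prof$rss)
  lower <- max(lo, grid[best] - options$grid_step)
  upper <- min(hi, grid[best] + options$grid_step)
  opt <- stats::optimize(function(e) profile_rss(e, conc, viab, options)$rss,
                         interval = c(lower, upper), tol = 1e-9)
  # keep whichever of grid point / refined point is better
  if (opt$objective <= prof$rss[best]) {
    e_hat <- opt$minimum
    rss <- opt$objective
  } else {
    e_hat <- grid[best]
    rss <- prof$rss[best]
  }
  at <- profile_rss(e_hat, conc, viab, options)
  top_hat <- at$top[1]
  converged <- is.finite(rss) && is.finite(e_hat) && is.finite(top_hat)

  out <- tibble::tibble(
    log10_ec50 = e_hat, ec50_um = 10^e_hat, top = top_hat, rss = rss,
    n_points = n, df = n - n_free, converged = converged,
    status = "fit")
  out$status <- no_fit_rule(conc, viab, out, options)
  if (out$status == "no_fit" && !out$converged) {
    out$log10_ec50 <- NA_real_
    out$ec50_um <- NA_real_
  }
  out
}

#' The no-fit rule
#'
#' A dilution series shows "no decrease in viability" — and therefore yields
#' no EC50 — when any of the following holds: (a) the optimizer did not
#' converge; (b) the mean viability at the highest tested concentration
#' exceeds `no_fit_viability_pct` (default 80 % of control); (c) the fitted
#' EC50 lies above the highest tested concentration. The two numeric teeth
#' of the verbal rule are module constants exposed in [fit_options()].
#'
#' @param concentration_um,viability_pct The series points.
#' @param candidate One-row tibble from the optimizer.
#' @param options See [fit_options()].
#' @return `"fit"` or `"no_fit"`.
#' @export
no_fit_rule <- function(concentration_um, viability_pct, candidate,
                        options = fit_options()) {
  top_dose <- max(concentration_um)
  mean_at_top <- mean(viability_pct[concentration_um == top_dose])
  if (!isTRUE(candidate$converged) ||
      mean_at_top > options$no_fit_viability_pct ||
      (is.finite(candidate$ec50_um) && candidate$ec50_um > top_dose)) {
    "no_fit"
  } else {
    "fit"
  }
}

#' Fit every dilution series in a normalized dataset
#'
#' Groups the output of [normalize_to_vehicle()] by the series key
#' `(cell_model, site, unit, compound, endpoint, exposure_h, run)` and fits
#' each series with [fit_series()].
#'
#' @param series_points Tibble from [normalize_to_vehicle()].
#' @param options See [fit_options()].
#' @return Tibble with one row per series: the key columns plus the
#'   [fit_series()] columns.
#' @export
fit_all <- function(series_points, options = fit_options()) {
  keys <- series_key_columns()
  grouped <- dplyr::group_by(series_points,
                             dplyr::across(dplyr::all_of(keys)))
  res <- dplyr::reframe(
    grouped,
    fit_series(.data$concentration_um, .data$viability_pct, options))
  tibble::as_tibble(res)
}
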