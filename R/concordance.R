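# Endpoint concordance (ATP vs resorufin) and 24 h vs 72 h paired testing.

#' Pearson correlation between the two viability endpoints
#'
#' Pairs observations measured by ATP and by resorufin at identical
#' experimental coordinates and returns their Pearson correlation. In
#' `"viability"` mode (default) the pairing is per well — same cell model,
#' site, unit, compound, exposure, concentration, run and technical
#' replicate — across all compounds, time points and cells. In `"ec50"`
#' mode, fitted `log10 EC50`s are paired per series key instead.
#'
#' @param x Normalized series points ([normalize_to_vehicle()]) for
#'   `mode = "viability"`, or fits ([fit_all()]) for `mode = "ec50"`.
#' @param mode `"viability"` or `"ec50"`.
#' @return List with `r`, `n` (number of matched pairs) and the matched
#'   tibble (`value_ATP`, `value_resorufin`).
#' @export
endpoint_correlation <- function(x, mode = c("viability", "ec50")) {
  mode <- match.arg(mode)
  if (mode == "viability") {
    id_cols <- c("cell_model", "site", "unit", "compound", "exposure_h",
                 "run", "concentration_um", "tech_rep")
    value <- "viability_pct"
  } else {
    x <- x[x$status == "fit", , drop = FALSE]
    id_cols <- c("cell_model", "site", "unit", "compound", "exposure_h",
                 "run")
    value <- "log10_ec50"
  }
  wide <- tidyr::pivot_wider(
    x[, c(id_cols, "endpoint", value)],
    names_from = "endpoint", values_from = dplyr::all_of(value),
    names_prefix = "value_")
  if (!all(c("value_ATP", "value_resorufin") %in% names(wide))) {
    stop("both endpoints must be present to correlate", call. = FALSE)
  }
  wide <- wide[stats::complete.cases(wide[, c("value_ATP",
                                              "value_resorufin")]), ]
  if (nrow(wide) < 3) {
    stop("fewer than 3 matched endpoint pairs", call. = FALSE)
  }
  list(r = stats::cor(wide$value_ATP, wide$value_resorufin),
       n = nrow(wide), pairs = tibble::as_tibble(wide))
}

#' Paired t-test of 24 h versus 72 h potency
#'
#' Matches fitted `log10 EC50`s across the two exposure times (same cell
#' model, site, unit, compound, endpoint and run) and applies a two-sided
#' paired Student's t-test to the differences. Pairs in which either time
#' point is `no_fit` are dropped and counted. If every difference is
#' identical the test statistic is degenerate; by convention the result is
#' then `p = 1` for a zero shift and `p = 0` (t infinite, sign of the
#' shift) for a nonzero constant shift.
#'
#' @param fits Output of [fit_all()] containing both exposure times.
#' @return List with `t`, `df`, `p_value`, `mean_diff` (mean
#'   `log10 EC50(72 h) - log10 EC50(24 h)`), `n_pairs`, `n_dropped`.
#' @export
paired_time_test <- function(fits) {
  id_cols <- c("cell_model", "site", "unit", "compound", "endpoint", "run")
  f <- fits[, c(id_cols, "exposure_h", "log10_ec50", "status")]
  wide <- tidyr::pivot_wider(
    f, names_from = "exposure_h",
    values_from = c("log10_ec50", "status"))
  need <- c("log10_ec50_24", "log10_ec50_72", "status_24", "status_72")
  if (!all(need %in% names(wide))) {
    stop("both 24 h and 72 h fits are required", call. = FALSE)
  }
  complete <- wide$status_24 == "fit" & wide$status_72 == "fit" &
    !is.na(wide$status_24) & !is.na(wide$status_72)
  n_dropped <- sum(!complete, na.rm = TRUE)
  d <- wide$log10_ec50_72[complete] - wide$log10_ec50_24[complete]
  if (length(d) < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  }
  list(t = t_stat, df = n - 1L, p_value = p, mean_diff = m,
       n_pairs = n, n_dropped = n_dropped)
}
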