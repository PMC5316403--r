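# Pairwise comparison of two dilution series: extra-sum-of-squares F-test
# of one shared curve (null) against separate curves (alternative), plus the
# dual significance rule p < 0.05 AND EC50 ratio > 3-fold.

#' Apply the dual significance rule
#'
#' Two dilution series are judged different only when the F-test is
#' significant (`p < alpha`, strict) and, to require biological relevance,
#' the relative EC50 difference exceeds the fold gate (`fold > fold_gate`,
#' strict; a fold of exactly 3 is not different).
#'
#' @param p P-value of the curve-comparison F-test.
#' @param fold EC50 fold-difference, `max(EC50_a/EC50_b, EC50_b/EC50_a)`.
#' @param alpha Significance level (default 0.05).
#' @param fold_gate Fold-change gate (default 3).
#' @return `"different"` or `"not_different"`.
#' @export
#' @examples
#' apply_rule(0.01, 5)    # "different"
#' apply_rule(0.01, 3.0)  # "not_different": the gate is strict
apply_rule <- function(p, fold, alpha = 0.05, fold_gate = 3) {
  stopifnot(is.finite(fold))
  if (is.finite(p) && p < alpha && fold > fold_gate) "different"
  else "not_different"
}

#' Compare two dilution series
#'
#' Both series are fitted separately and jointly with the constrained
#' sigmoid. The null model fits one shared `(Top, log10 EC50)` to the pooled
#' points (`rss_0`, `df_0 = n_a + n_b - 2`); the alternative is the pair of
#' separate fits (`rss_1 = rss_a + rss_b`, `df_1 = n_a + n_b - 4`). Then
#' `F = ((rss_0 - rss_1) / (df_0 - df_1)) / (rss_1 / df_1)` with p from the
#' upper tail of the F distribution. If either series is `no_fit` the
#' verdict is `no_fit` and no statistics are reported. Degenerate
#' zero-residual comparisons resolve by the continuous limit (F to
#' infinity, p to 0): the verdict is decided by the fold gate alone.
#'
#' @param a,b Each a tibble/data.frame of points with columns
#'   `concentration_um` and `viability_pct` (one series each).
#' @param options Fit options ([fit_options()]).
#' @param alpha,fold_gate Dual-rule constants.
#' @return One-row tibble: `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `fold_diff`, `verdict` (`different`, `not_different` or `no_fit`), and
#'   the two separate fits' `log10_ec50` as `log10_ec50_a`, `log10_ec50_b`.
#' @export
compare_series <- function(a, b, options = fit_options(),
                           alpha = 0.05, fold_gate = 3) {
  fit_a <- fit_series(a$concentration_um, a$viability_pct, options)
  fit_b <- fit_series(b$concentration_um, b$viability_pct, options)
  compare_fitted(fit_a, fit_b,
                 pooled_conc = c(a$concentration_um, b$concentration_um),
                 pooled_viab = c(a$viability_pct, b$viability_pct),
                 options = options, alpha = alpha, fold_gate = fold_gate)
}

# Core comparison given the two separate fits and the pooled points.
compare_fitted <- function(fit_a, fit_b, pooled_conc, pooled_viab,
                           options = fit_options(),
                           alpha = 0.05, fold_gate = 3) {
  empty <- tibble::tibble(
    f_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
    p_value = NA_real_, fold_diff = NA_real_, verdict = "no_fit",
    log10_ec50_a = fit_a$log10_ec50, log10_ec50_b = fit_b$log10_ec50)
  if (fit_a$status == "no_fit" || fit_b$status == "no_fit") {
    return(empty)
  }
  n_free <- if (is.null(options$fix_top)) 2L else 1L
  pooled <- fit_series(pooled_conc, pooled_viab, options)
  rss0 <- pooled$rss
  df0 <- length(pooled_viab) - n_free
  rss1 <- fit_a$rss + fit_b$rss
  df1 <- length(pooled_viab) - 2L * n_free
  if (df1 < 1L) stop("under-determined comparison: df < 1", call. = FALSE)
  # nested models: the shared fit can never beat the separate fits
  rss0 <- max(rss0, rss1)
  fold <- 10^abs(fit_a$log10_ec50 - fit_b$log10_ec50)
  df_num <- df0 - df1
  if (rss1 <= .Machine$double.eps * max(1, rss0)) {
    if (rss0 - rss1 <= .Machine$double.eps) {
      f_stat <- 0
      p <- 1
    } else {
      f_stat <- Inf
      p <- 0
    }
  } else {
    f_stat <- ((rss0 - rss1) / df_num) / (rss1 / df1)
    p <- stats::pf(f_stat, df_num, df1, lower.tail = FALSE)
  }
  tibble::tibble(
    f_stat = f_stat, df_num = as.integer(df_num), df_den = as.integer(df1),
    p_value = p, fold_diff = fold,
    verdict = apply_rule(p, fold, alpha, fold_gate),
    log10_ec50_a = fit_a$log10_ec50, log10_ec50_b = fit_b$log10_ec50)
}

#' Compare many enumerated pairs of fitted series
#'
#' Runs [compare_series()] for each row of a pair listing (as produced by
#' [enumerate_pairs()]), pulling the series points from the normalized data.
#'
#' @param series_points Tibble from [normalize_to_vehicle()].
#' @param pairs Tibble with columns `key_a` and `key_b`, each a series key
#'   string as produced by [series_key()].
#' @param options,alpha,fold_gate Passed to [compare_series()].
#' @return `pairs` with the comparison statistics bound on.
#' @export
compare_pairs <- function(series_points, pairs, options = fit_options(),
                          alpha = 0.05, fold_gate = 3) {
  if (nrow(pairs) == 0) {
    return(dplyr::bind_cols(pairs, tibble::tibble(
      f_stat = numeric(0), df_num = integer(0), df_den = integer(0),
      p_value = numeric(0), fold_diff = numeric(0), verdict = character(0),
      log10_ec50_a = numeric(0), log10_ec50_b = numeric(0))))
  }
  keyed <- split(series_points, series_key(series_points))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- keyed[[pairs$key_a[i]]]
    b <- keyed[[pairs$key_b[i]]]
    if (is.null(a) || is.null(b)) {
      stop("pair references an unknown series key: ",
           pairs$key_a[i], " / ", pairs$key_b[i], call. = FALSE)
    }
    compare_series(a, b, options, alpha, fold_gate)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}

#' Canonical series key string
#'
#' @param x Tibble carrying the series key columns.
#' @return Character vector, one `|`-joined key per row.
#' @export
series_key <- function(x) {
  do.call(paste, c(unname(as.list(x[, series_key_columns()])), sep = "|"))
}
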