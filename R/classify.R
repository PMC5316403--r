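# EC50/Cmax margin-of-safety classification and DILI separation diagnostics.

#' Aggregate fitted EC50s per compound and cell model
#'
#' Summarizes per-series fits into one EC50 per
#' `(compound, cell_model, endpoint, exposure_h)` cell by averaging
#' `log10 EC50` over all series with `status == "fit"` (a geometric mean on
#' the concentration scale, matching how multi-site determinations are
#' usually combined). Cells where every series is `no_fit` keep
#' `status = "no_fit"` and no EC50.
#'
#' @param fits Output of [fit_all()].
#' @param by Grouping columns; add `"unit"` or `"site"` to keep
#'   per-instance EC50s.
#' @return Tibble with grouping columns, `log10_ec50`, `ec50_um`,
#'   `n_series`, `n_fit` and `status`.
#' @export
aggregate_ec50 <- function(fits, by = c("compound", "cell_model",
                                        "endpoint", "exposure_h")) {
  grouped <- dplyr::group_by(fits, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n_series = dplyr::n(),
    n_fit = sum(.data$status == "fit"),
    log10_ec50 = ifelse(sum(.data$status == "fit") > 0,
                        mean(.data$log10_ec50[.data$status == "fit"]),
                        NA_real_),
    .groups = "drop")
  out$ec50_um <- 10^out$log10_ec50
  out$status <- ifelse(out$n_fit > 0, "fit", "no_fit")
  out
}

#' Compute EC50/Cmax safety margins
#'
#' Divides each aggregated EC50 by the compound's peak therapeutic plasma
#' concentration Cmax (both µM). Compounds whose series were all `no_fit`
#' get no margin and can never be classified toxic: within the tested range
#' they showed no measurable cytotoxicity.
#'
#' @param ec50s Aggregated EC50 tibble ([aggregate_ec50()]) with a
#'   `compound` column.
#' @param panel Compound panel ([load_panel()]).
#' @return `ec50s` with `dili_label`, `cmax_um` and `margin` columns.
#' @export
compute_margins <- function(ec50s, panel) {
  unknown <- setdiff(unique(ec50s$compound), panel$name)
  if (length(unknown)) {
    stop("compounds missing from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(ec50s$compound, panel$name)
  out <- ec50s
  out$dili_label <- panel$dili_label[idx]
  out$cmax_um <- panel$cmax_um[idx]
  out$margin <- out$ec50_um / out$cmax_um
  out
}

#' Classify compounds as potentially hepatotoxic by safety margin
#'
#' A compound is flagged toxic when its margin falls strictly below the
#' threshold (`margin < threshold`; an exact tie is non-toxic). No-fit
#' compounds carry `NA`.
#'
#' @param margins Output of [compute_margins()].
#' @param threshold Positive margin threshold (default 20).
#' @return `margins` with a logical `classified_toxic` column.
#' @export
#' @examples
#' panel <- load_panel()
#' m <- compute_margins(tibble::tibble(compound = "amiodarone",
#'                                     ec50_um = 16.14, status = "fit"), panel)
#' classify_margins(m)$classified_toxic
classify_margins <- function(margins, threshold = 20) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  margins$classified_toxic <- ifelse(is.na(margins$margin), NA,
                                     margins$margin < threshold)
  margins
}

#' Sensitivity/specificity sweep over margin thresholds
#'
#' For each threshold, counts DILI and non-DILI compounds flagged toxic and
#' reports sensitivity (flagged DILI / all DILI) and specificity (unflagged
#' non-DILI / all non-DILI). No-fit compounds cannot be flagged (they are
#' excluded from numerators) but remain in the denominators.
#'
#' @param margins Output of [compute_margins()] — one row per compound.
#' @param thresholds Numeric vector of positive thresholds.
#' @return Tibble with `threshold`, `n_dili_flagged`, `n_nondili_flagged`,
#'   `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(margins, thresholds = c(1, 2, 5, 10, 20, 50, 100)) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0))
  n_dili <- sum(margins$dili_label == "DILI")
  n_nondili <- sum(margins$dili_label == "non-DILI")
  rows <- lapply(sort(thresholds), function(th) {
    cl <- classify_margins(margins, th)
    flagged <- !is.na(cl$classified_toxic) & cl$classified_toxic
    nd <- sum(flagged & cl$dili_label == "DILI")
    nn <- sum(flagged & cl$dili_label == "non-DILI")
    tibble::tibble(threshold = th, n_dili_flagged = nd,
                   n_nondili_flagged = nn,
                   sensitivity = nd / n_dili,
                   specificity = (n_nondili - nn) / n_nondili)
  })
  dplyr::bind_rows(rows)
}

#' Can a single EC50 cutoff separate DILI from non-DILI compounds?
#'
#' Tests whether any one threshold on the raw EC50 values perfectly splits
#' the two labels (DILI below, non-DILI above — the direction in which
#' toxicity is informative), and counts label inversions: (DILI, non-DILI)
#' pairs in which the DILI compound is the *less* potent one. No-fit
#' compounds are placed above every fitted EC50.
#'
#' @param ec50s Tibble with `compound`, `dili_label`, `log10_ec50` (NA for
#'   no-fit) columns, one row per compound.
#' @return List with `separable` (logical), `n_inversions`, and
#'   `n_pairs` (total DILI x non-DILI pairs).
#' @export
separation_check <- function(ec50s) {
  stopifnot(all(c("dili_label", "log10_ec50") %in% names(ec50s)))
  v <- ec50s$log10_ec50
  if (all(is.na(v))) stop("no fitted EC50s to assess", call. = FALSE)
  sentinel <- max(v, na.rm = TRUE) + 1
  v[is.na(v)] <- sentinel
  dili <- v[ec50s$dili_label == "DILI"]
  nond <- v[ec50s$dili_label == "non-DILI"]
  if (length(dili) == 0 || length(nond) == 0) {
    stop("need at least one compound per label", call. = FALSE)
  }
  inv <- sum(outer(dili, nond, ">"))
  list(separable = max(dili) < min(nond),
       n_inversions = inv,
       n_pairs = length(dili) * length(nond))
}
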