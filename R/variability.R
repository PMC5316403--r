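# Reproducibility strata and variability coefficients. The coefficient is
# the fraction of pairwise curve comparisons judged "different"; no-fit
# pairs stay in the denominator.

strata <- function() {
  c("inter_lab", "intra_lab", "inter_donor", "clone", "fresh_vs_cryo")
}

#' Enumerate pairwise comparisons for a reproducibility stratum
#'
#' Given fitted series (or any table carrying the full series key columns),
#' lists every unordered pair of series the stratum compares:
#'
#' * `inter_lab` — site pairs within
#'   `(cell_model, unit, compound, endpoint, exposure_h, run)`;
#' * `intra_lab` — run pairs within
#'   `(cell_model, site, unit, compound, endpoint, exposure_h)`;
#' * `inter_donor` — donor (unit) pairs within primary-hepatocyte models,
#'   per `(cell_model, compound, endpoint, exposure_h, run)`; sites may
#'   differ because donors are allocated to sites;
#' * `clone` — HepG2_ECACC versus HepG2_TS within
#'   `(site, compound, endpoint, exposure_h, run)`;
#' * `fresh_vs_cryo` — fresh versus cryopreserved variants of the same cell
#'   type per `(compound, endpoint, exposure_h, run)`.
#'
#' @param fits Tibble with the series key columns (typically [fit_all()]
#'   output).
#' @param stratum One of `"inter_lab"`, `"intra_lab"`, `"inter_donor"`,
#'   `"clone"`, `"fresh_vs_cryo"`.
#' @return Tibble with columns `key_a`, `key_b` (canonical [series_key()]
#'   strings, `key_a < key_b`) plus the grouping columns. Empty, with a
#'   warning, when the stratum has fewer than two comparable groups.
#' @export
enumerate_pairs <- function(fits, stratum = strata()) {
  stratum <- match.arg(stratum)
  x <- tibble::as_tibble(fits[, series_key_columns()])
  x$key <- series_key(x)

  scheme <- switch(
    stratum,
    inter_lab = list(
      subset = rep(TRUE, nrow(x)),
      fixed = c("cell_model", "unit", "compound", "endpoint", "exposure_h",
                "run"),
      vary = "site"),
    intra_lab = list(
      subset = rep(TRUE, nrow(x)),
      fixed = c("cell_model", "site", "unit", "compound", "endpoint",
                "exposure_h"),
      vary = "run"),
    inter_donor = list(
      subset = x$cell_model %in% c("PHH_cryo", "PHH_fresh"),
      fixed = c("cell_model", "compound", "endpoint", "exposure_h", "run"),
      vary = "unit"),
    clone = list(
      subset = x$cell_model %in% c("HepG2_ECACC", "HepG2_TS"),
      fixed = c("site", "compound", "endpoint", "exposure_h", "run"),
      vary = "cell_model"),
    fresh_vs_cryo = list(
      subset = x$cell_model %in% c("PHH_cryo", "PHH_fresh",
                                   "HepaRG_cryo", "HepaRG_fresh"),
      fixed = c("compound", "endpoint", "exposure_h", "run"),
      vary = "cell_model"))

  y <- x[scheme$subset, , drop = FALSE]
  if (stratum == "fresh_vs_cryo" && nrow(y)) {
    y$cell_type <- sub("_(cryo|fresh)$", "", y$cell_model)
    scheme$fixed <- c(scheme$fixed, "cell_type")
  }
  if (nrow(y) == 0 || length(unique(y[[scheme$vary]])) < 2) {
    warning("stratum '", stratum, "' has fewer than 2 comparable groups")
    return(tibble::tibble(key_a = character(0), key_b = character(0)))
  }
  groups <- split(y, y[, scheme$fixed], drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g[[scheme$vary]], g$key), , drop = FALSE]
    if (stratum %in% c("clone", "fresh_vs_cryo")) {
      # only pairs across the two variants, not within
      a <- g[g[[scheme$vary]] %in% c("HepG2_ECACC", "PHH_fresh",
                                   "HepaRG_fresh"), , drop = FALSE]
      b <- g[!g$key %in% a$key, , drop = FALSE]
      if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
      cross <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      ka <- a$key[cross$i]; kb <- b$key[cross$j]
    } else {
      if (nrow(g) < 2) return(NULL)
      cmb <- utils::combn(seq_len(nrow(g)), 2)
      keep <- g[[scheme$vary]][cmb[1, ]] != g[[scheme$vary]][cmb[2, ]]
      if (!any(keep)) return(NULL)
      ka <- g$key[cmb[1, keep]]; kb <- g$key[cmb[2, keep]]
    }
    swap <- ka > kb
    tibble::tibble(key_a = ifelse(swap, kb, ka),
                   key_b = ifelse(swap, ka, kb),
                   g[rep(1L, length(ka)), scheme$fixed, drop = FALSE])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    warning("stratum '", stratum, "' has fewer than 2 comparable groups")
    return(tibble::tibble(key_a = character(0), key_b = character(0)))
  }
  res <- res[order(res$key_a, res$key_b), , drop = FALSE]
  res$cell_type <- NULL
  tibble::remove_rownames(res)
}

#' Variability coefficient of a set of pairwise comparisons
#'
#' The coefficient divides the number of comparisons judged significantly
#' different by the number of all pairwise comparisons. No-fit pairs count
#' in the denominator (they are comparisons that were made) and are reported
#' as their own category.
#'
#' @param comparisons Tibble with a `verdict` column (`different`,
#'   `not_different`, `no_fit`), e.g. from [compare_pairs()].
#' @param stratum Optional stratum label to carry through.
#' @param by Optional character vector of grouping columns (e.g.
#'   `"compound"`) for per-group coefficients in addition to the aggregate.
#' @return Tibble with `stratum`, grouping columns (aggregate rows carry
#'   `NA`), `n_total`, `n_different`, `n_not_different`, `n_no_fit` and
#'   `coefficient`.
#' @export
#' @examples
#' variability_coefficient(tibble::tibble(
#'   verdict = c("different", "not_different", "not_different", "no_fit")))
variability_coefficient <- function(comparisons, stratum = NA_character_,
                                    by = NULL) {
  if (nrow(comparisons) == 0) {
    stop("cannot compute a variability coefficient from zero comparisons",
         call. = FALSE)
  }
  stopifnot(all(comparisons$verdict %in%
                  c("different", "not_different", "no_fit")))
  summarise_one <- function(d) {
    tibble::tibble(
      n_total = nrow(d),
      n_different = sum(d$verdict == "different"),
      n_not_different = sum(d$verdict == "not_different"),
      n_no_fit = sum(d$verdict == "no_fit"),
      coefficient = sum(d$verdict == "different") / nrow(d))
  }
  agg <- summarise_one(comparisons)
  agg <- dplyr::bind_cols(tibble::tibble(stratum = stratum), agg)
  if (is.null(by)) return(agg)
  grouped <- dplyr::group_by(comparisons,
                             dplyr::across(dplyr::all_of(by)))
  per <- dplyr::reframe(grouped, summarise_one(dplyr::pick(dplyr::everything())))
  per <- dplyr::bind_cols(tibble::tibble(stratum = rep(stratum, nrow(per))),
                          per)
  dplyr::bind_rows(per, agg)
}
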