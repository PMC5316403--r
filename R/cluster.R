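# EC50 profile matrix and hierarchical clustering of cell-model instances.
# Rows are compounds, columns are cell-model instances; rows are
# mean-centered and sigma-normalized (z-scored) before clustering with
# complete (maximum) linkage.

#' Build the compound x cell-model EC50 matrix
#'
#' @param fits Output of [fit_all()].
#' @param endpoint,exposure_h Which endpoint/time slice to use.
#' @param columns `"cell_model"` for one column per model, or `"instance"`
#'   for one column per `cell_model:unit` combination (donor-level columns
#'   for primary hepatocytes).
#' @return Numeric matrix of `log10 EC50` values (compounds x columns) with
#'   `NA` for cells whose series were all no-fit.
#' @export
build_ec50_matrix <- function(fits, endpoint = "ATP", exposure_h = 72,
                              columns = c("instance", "cell_model")) {
  columns <- match.arg(columns)
  f <- fits[fits$endpoint == endpoint & fits$exposure_h == exposure_h, ,
            drop = FALSE]
  if (nrow(f) == 0) stop("no fits for the requested endpoint/time",
                         call. = FALSE)
  by <- if (columns == "instance") c("compound", "cell_model", "unit")
        else c("compound", "cell_model")
  agg <- aggregate_ec50(f, by = c(by, "endpoint", "exposure_h"))
  agg$column <- if (columns == "instance") {
    paste(agg$cell_model, agg$unit, sep = ":")
  } else {
    agg$cell_model
  }
  wide <- tidyr::pivot_wider(agg[, c("compound", "column", "log10_ec50")],
                             names_from = "column",
                             values_from = "log10_ec50")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$compound
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  m
}

#' Handle missing (no-fit) cells in an EC50 matrix
#'
#' `drop_row` removes compounds with any missing cell;
#' `censor_at_max_dose` substitutes `log10` of the compound's highest tested
#' concentration — the value is right-censored at the top of the dose range —
#' and records which cells were censored in the `"censored"` attribute.
#'
#' @param m EC50 matrix from [build_ec50_matrix()].
#' @param policy `"drop_row"` or `"censor_at_max_dose"`.
#' @param panel Compound panel; required for the censor policy.
#' @return The completed matrix.
#' @export
impute_missing <- function(m, policy = c("drop_row", "censor_at_max_dose"),
                           panel = NULL) {
  policy <- match.arg(policy)
  if (!anyNA(m)) return(m)
  if (policy == "drop_row") {
    return(m[stats::complete.cases(m), , drop = FALSE])
  }
  if (is.null(panel)) stop("censor_at_max_dose requires the panel",
                           call. = FALSE)
  censored <- which(is.na(m), arr.ind = TRUE)
  max_dose <- vapply(panel$concentrations_um, max, numeric(1))
  names(max_dose) <- panel$name
  for (k in seq_len(nrow(censored))) {
    comp <- rownames(m)[censored[k, "row"]]
    m[censored[k, "row"], censored[k, "col"]] <- log10(max_dose[[comp]])
  }
  attr(m, "censored") <- censored
  m
}

#' Cluster cell-model cytotoxicity profiles
#'
#' Each compound row is z-scored (mean-centered, divided by its standard
#' deviation); zero-variance rows are dropped with a warning. Pairwise
#' distances between columns use the chosen metric (`euclidean` by default;
#' `chebyshev` — the maximum coordinate difference — is also available since
#' "maximum" naming is ambiguous between linkage and metric), and clusters
#' are agglomerated by complete (maximum) linkage.
#'
#' @param m Complete EC50 matrix (no `NA`; see [impute_missing()]).
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return List with `hclust` (the merge tree), `newick` (the dendrogram as
#'   a Newick string with branch lengths derived from merge heights),
#'   `zmatrix` (the z-scored matrix) and `metric`.
#' @export
cluster_models <- function(m, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  if (anyNA(m)) stop("matrix contains missing cells; apply impute_missing()",
                     call. = FALSE)
  if (ncol(m) < 2 || nrow(m) < 2) {
    stop("clustering needs at least 2 columns and 2 complete rows",
         call. = FALSE)
  }
  rsd <- apply(m, 1, stats::sd)
  if (any(rsd == 0)) {
    warning("dropping zero-variance rows: ",
            paste(rownames(m)[rsd == 0], collapse = ", "))
    m <- m[rsd > 0, , drop = FALSE]
    if (nrow(m) < 2) stop("all rows dropped; nothing to cluster",
                          call. = FALSE)
  }
  z <- t(scale(t(m)))
  d <- stats::dist(t(z),
                   method = if (metric == "chebyshev") "maximum"
                            else "euclidean")
  hc <- stats::hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), zmatrix = z,
       metric = metric)
}

#' Column labels of the two top-level clusters
#'
#' Cuts the merge tree at two clusters and returns the column labels of
#' each, useful for checking which cell models the top split separates.
#'
#' @param clustering Result of [cluster_models()].
#' @return List of two character vectors.
#' @export
top_split <- function(clustering) {
  k <- stats::cutree(clustering$hclust, k = 2)
  split(names(k), unname(k))
}
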