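# Compound panel: the 13 training compounds with dose grids and Cmax values.

#' Load the packaged compound panel
#'
#' Returns the 13-compound training panel used throughout the pipeline: nine
#' compounds implicated in human drug-induced liver injury (DILI) and four
#' without known DILI liability, each with its 7-point final dose
#' concentration grid (µM), its peak therapeutic plasma concentration Cmax
#' (µM), and the postulated hepatotoxicity mechanism codes
#' (a: reactive metabolites, b: mitochondrial dysfunction, c: BSEP
#' inhibition, d: lysosomal dysfunction, e: immune-mediated).
#'
#' @param path Optional path to a panel CSV with columns
#'   `name, dili_label, c1..c7, cmax_um, mechanisms`; defaults to the
#'   packaged panel. Supplying a custom file supports new chemical entities
#'   with predicted Cmax values.
#' @return A tibble with one row per compound and columns `name`,
#'   `dili_label` (`"DILI"` or `"non-DILI"`), `concentrations_um` (list
#'   column of 7 increasing doses), `cmax_um`, `mechanism_codes` (list column
#'   of single-letter codes, empty for non-DILI compounds).
#' @export
#' @examples
#' panel <- load_panel()
#' panel$concentrations_um[[match("amiodarone", panel$name)]]
load_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_panel.csv",
                        package = "cytotoxpanel", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("compound panel fixture not found; the installation is corrupt",
         call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(mechanisms = "character"))
  required <- c("name", "dili_label", paste0("c", 1:7), "cmax_um", "mechanisms")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("panel file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conc <- lapply(seq_len(nrow(raw)), function(i) {
    as.numeric(raw[i, paste0("c", 1:7)])
  })
  panel <- tibble::tibble(
    name = raw$name,
    dili_label = raw$dili_label,
    concentrations_um = conc,
    cmax_um = as.numeric(raw$cmax_um),
    mechanism_codes = lapply(raw$mechanisms, function(m) {
      if (is.na(m) || !nzchar(m)) character(0) else strsplit(m, "")[[1]]
    })
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(all(panel$dili_label %in% c("DILI", "non-DILI")))
  for (i in seq_len(nrow(panel))) {
    cc <- panel$concentrations_um[[i]]
    if (length(cc) != 7L || any(!is.finite(cc)) || any(cc <= 0) ||
        any(diff(cc) <= 0)) {
      stop("panel entry '", panel$name[i],
           "' must have 7 strictly increasing positive doses", call. = FALSE)
    }
    if (!is.finite(panel$cmax_um[i]) || panel$cmax_um[i] <= 0) {
      stop("panel entry '", panel$name[i], "' has invalid cmax_um",
           call. = FALSE)
    }
    if (panel$dili_label[i] == "non-DILI" &&
        length(panel$mechanism_codes[[i]]) > 0) {
      stop("non-DILI compound '", panel$name[i],
           "' must not carry mechanism codes", call. = FALSE)
    }
  }
  invisible(panel)
}
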