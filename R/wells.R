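# Tidy well-level interchange format: one row per well, comma-separated,
# UTF-8, header mandatory, decimal point. All concentrations are µM.

#' Read well-level plate measurements from CSV
#'
#' The interchange format has exactly one row per well and the columns
#' `cell_model, site, unit, compound, endpoint, exposure_h, concentration_um,
#' run, tech_rep, signal`. Vehicle-control wells carry `compound = "vehicle"`
#' and `concentration_um = 0`; they define 100 % viability for their block.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of well measurements.
#' @seealso [write_wells()], [validate_wells()]
#' @export
read_wells <- function(path) {
  if (!file.exists(path)) stop("wells file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(well_columns(), names(raw))
  if (length(missing)) {
    stop("wells file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wells <- tibble::as_tibble(raw[, well_columns()])
  wells$exposure_h <- as.integer(wells$exposure_h)
  wells$run <- as.integer(wells$run)
  wells$tech_rep <- as.integer(wells$tech_rep)
  wells$concentration_um <- as.numeric(wells$concentration_um)
  wells$signal <- as.numeric(wells$signal)
  validate_wells(wells)
}

#' Write well-level measurements to CSV
#'
#' @param wells A tibble of well measurements.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  wells <- validate_wells(wells)
  utils::write.csv(as.data.frame(wells), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a table of well measurements
#'
#' Checks the column contract and the row-level invariants: known cell-model
#' and endpoint codes, exposure time 24 or 72 h, non-negative signal,
#' technical replicate index in 1..3, and the vehicle convention
#' (`concentration_um == 0` exactly for `compound == "vehicle"`). Violations
#' are reported with the offending row numbers.
#'
#' @param wells A data frame of well measurements.
#' @return The validated tibble (invisibly convertible), with columns in
#'   canonical order.
#' @export
validate_wells <- function(wells) {
  missing <- setdiff(well_columns(), names(wells))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wells <- tibble::as_tibble(wells)[, well_columns()]
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      if (length(rows) > 5) shown <- paste0(shown, ", ...")
      problems <<- c(problems, sprintf("%s (rows %s)", what, shown))
    }
  }
  flag(!wells$cell_model %in% cell_models(), "unknown cell_model")
  flag(!wells$endpoint %in% endpoints(), "unknown endpoint")
  flag(!wells$exposure_h %in% exposure_times(), "exposure_h not 24 or 72")
  flag(!is.finite(wells$signal) | wells$signal < 0, "negative or missing signal")
  flag(!is.finite(wells$concentration_um) | wells$concentration_um < 0,
       "negative or missing concentration_um")
  flag(!wells$tech_rep %in% 1:3, "tech_rep outside 1..3")
  flag(!is.finite(wells$run) | wells$run < 1, "run must be a positive integer")
  is_vehicle <- wells$compound == "vehicle"
  flag(is_vehicle & wells$concentration_um != 0,
       "vehicle wells must have concentration_um = 0")
  flag(!is_vehicle & wells$concentration_um == 0,
       "zero concentration requires compound = 'vehicle'")
  if (length(problems)) {
    stop("invalid well measurements:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  wells
}
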