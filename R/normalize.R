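# Vehicle normalization: percent viability relative to the vehicle-control
# mean of the same experimental block.

#' Normalize raw signals to vehicle control
#'
#' Converts raw well signals into percent viability,
#' `100 * signal / mean(vehicle signals)`, where the vehicle mean is taken
#' over the vehicle wells of the same block
#' `(cell_model, site, unit, endpoint, exposure_h, run)` — vehicle wells are
#' shared across compounds within a block. Technical replicates are retained
#' as separate points; nothing is pre-averaged, so each replicate later
#' contributes its own residual (and degree of freedom) to curve fitting.
#'
#' @param wells Validated well tibble (see [read_wells()]).
#' @param min_vehicle Minimum number of vehicle wells a block must contain.
#' @return A tibble of dilution-series points with the series key columns
#'   `cell_model, site, unit, compound, endpoint, exposure_h, run` plus
#'   `concentration_um`, `tech_rep` and `viability_pct`.
#' @export
normalize_to_vehicle <- function(wells, min_vehicle = 3L) {
  wells <- validate_wells(wells)
  veh <- wells[wells$compound == "vehicle", , drop = FALSE]
  trt <- wells[wells$compound != "vehicle", , drop = FALSE]
  if (nrow(trt) == 0) stop("no treated wells to normalize", call. = FALSE)

  veh_means <- dplyr::summarise(
    dplyr::group_by(veh, dplyr::across(dplyr::all_of(block_columns()))),
    vehicle_mean = mean(.data$signal),
    n_vehicle = dplyr::n(),
    .groups = "drop")

  out <- dplyr::left_join(trt, veh_means, by = block_columns())
  bad <- is.na(out$vehicle_mean) | out$n_vehicle < min_vehicle
  if (any(bad)) {
    blocks <- unique(out[bad, block_columns()])
    stop("blocks without sufficient vehicle wells (need >= ", min_vehicle,
         "): ",
         paste(apply(blocks, 1, paste, collapse = "/"), collapse = "; "),
         call. = FALSE)
  }
  if (any(out$vehicle_mean <= 0)) {
    stop("vehicle mean signal is not positive in at least one block",
         call. = FALSE)
  }
  out$viability_pct <- 100 * out$signal / out$vehicle_mean
  out <- out[order(out$cell_model, out$site, out$unit, out$compound,
                   out$endpoint, out$exposure_h, out$run,
                   out$concentration_um, out$tech_rep), ]
  tibble::as_tibble(out[, c(series_key_columns(),
                            "concentration_um", "tech_rep", "viability_pct")])
}
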