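# Synthetic multicenter plate-data generator with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# per-compound x per-cell-model true EC50s, horizontal (log10 EC50) shifts
# for sites, donors/clones/lots and runs, additive Gaussian well noise on
# percent viability (truncated at 0), lognormal vehicle-signal noise, flat
# non-responders, and triplicate dosing on each compound's 7-point grid.

#' Default generator parameters
#'
#' Builds the parameter list consumed by [generate_dataset()]. True EC50s are
#' placed per compound at a fixed position of its own dose grid (default the
#' 5th of 7 concentrations) and shifted per cell model; laboratory, donor/
#' clone and run effects act on log10 EC50, i.e. as horizontal curve shifts.
#'
#' @param panel Compound panel from [load_panel()].
#' @param base_dose_index Which grid position anchors the true EC50 (1-7).
#' @param model_offset_log10 Named numeric, additional log10 EC50 offset per
#'   cell model (unnamed models get 0).
#' @param non_responders Character vector of compounds generated flat at
#'   `true_top` (no concentration dependence), emulating compounds for which
#'   no toxicity is detectable within the tested range.
#' @param true_top Upper viability plateau in percent.
#' @param time_shift_log10 log10 EC50 increment applied at 24 h relative to
#'   the 72 h reference (shorter exposure is less sensitive).
#' @param site_shift_sd,unit_shift_sd,run_shift_sd Standard deviations
#'   (log10 units) of the Gaussian site, unit (donor/clone/lot) and run
#'   effects.
#' @param noise_sd_pct Standard deviation of the additive Gaussian well noise
#'   on percent viability.
#' @param vehicle_signal_mean Mean raw vehicle signal, a scalar or named per
#'   endpoint (arbitrary instrument units).
#' @param vehicle_cv Coefficient of variation of the lognormal well-to-well
#'   vehicle signal noise.
#' @param truth_log10_ec50 Optional tibble `(compound, cell_model,
#'   true_log10_ec50)` overriding the base + offset placement.
#' @return A named list of generator parameters.
#' @export
default_params <- function(panel,
                           base_dose_index = 5L,
                           model_offset_log10 = c(PHH_cryo = 0, PHH_fresh = 0,
                                                  HepG2_ECACC = 0.3,
                                                  HepG2_TS = 0.3,
                                                  HepaRG_cryo = 0.15,
                                                  HepaRG_fresh = 0.15,
                                                  Upcyte = 0.3),
                           non_responders = "ximelagatran",
                           true_top = 100,
                           time_shift_log10 = 0.3,
                           site_shift_sd = 0.15,
                           unit_shift_sd = 0.05,
                           run_shift_sd = 0.05,
                           noise_sd_pct = 5,
                           vehicle_signal_mean = c(ATP = 20000,
                                                   resorufin = 5000),
                           vehicle_cv = 0.1,
                           truth_log10_ec50 = NULL) {
  base <- vapply(panel$concentrations_um,
                 function(cc) log10(cc[[base_dose_index]]), numeric(1))
  names(base) <- panel$name
  list(base_log10_ec50 = base,
       model_offset_log10 = model_offset_log10,
       non_responders = non_responders,
       true_top = true_top,
       time_shift_log10 = time_shift_log10,
       site_shift_sd = site_shift_sd,
       unit_shift_sd = unit_shift_sd,
       run_shift_sd = run_shift_sd,
       noise_sd_pct = noise_sd_pct,
       vehicle_signal_mean = vehicle_signal_mean,
       vehicle_cv = vehicle_cv,
       truth_log10_ec50 = truth_log10_ec50)
}

#' Default multicenter study design
#'
#' Three test sites for the primary-hepatocyte-like and HepG2-like models and
#' two for the others, with a donor allocation in which one reference donor
#' is shared by all PHH sites and the remaining donors are site-specific.
#'
#' @param n_runs Independent biological replicate experiments per block.
#' @param study_endpoints Endpoints to generate.
#' @param study_times Exposure times (h) to generate.
#' @param n_vehicle Vehicle wells per block (>= 6).
#' @return A design list with elements `blocks` (tibble `cell_model, site,
#'   unit`), `n_runs`, `endpoints`, `exposure_h`, `n_vehicle`.
#' @export
default_design <- function(n_runs = 2L,
                           study_endpoints = endpoints(),
                           study_times = exposure_times(),
                           n_vehicle = 6L) {
  blocks <- tibble::tribble(
    ~cell_model,   ~site, ~unit,
    "PHH_cryo",    "S1",  "D_B17",
    "PHH_cryo",    "S2",  "D_B17",
    "PHH_cryo",    "S2",  "D_M16",
    "PHH_cryo",    "S2",  "D_S1100",
    "PHH_cryo",    "S3",  "D_B17",
    "PHH_cryo",    "S3",  "D_S1070",
    "PHH_cryo",    "S3",  "D_S1099",
    "HepG2_ECACC", "S1",  "ECACC",
    "HepG2_ECACC", "S2",  "ECACC",
    "HepG2_ECACC", "S3",  "ECACC",
    "HepaRG_cryo", "S1",  "HPR116",
    "HepaRG_cryo", "S2",  "HPR116",
    "Upcyte",      "S1",  "422A",
    "Upcyte",      "S2",  "422A"
  )
  list(blocks = blocks, n_runs = as.integer(n_runs),
       endpoints = study_endpoints, exposure_h = as.integer(study_times),
       n_vehicle = as.integer(n_vehicle))
}

truth_table <- function(panel, design, params) {
  models <- unique(design$blocks$cell_model)
  grid <- expand.grid(compound = panel$name, cell_model = models,
                      stringsAsFactors = FALSE)
  offset <- params$model_offset_log10
  off <- ifelse(grid$cell_model %in% names(offset),
                unname(offset[grid$cell_model]), 0)
  truth <- tibble::tibble(
    compound = grid$compound,
    cell_model = grid$cell_model,
    true_log10_ec50 = unname(params$base_log10_ec50[grid$compound]) + off,
    true_top = params$true_top
  )
  if (!is.null(params$truth_log10_ec50)) {
    ov <- params$truth_log10_ec50
    idx <- match(paste(truth$compound, truth$cell_model),
                 paste(ov$compound, ov$cell_model))
    hit <- !is.na(idx)
    truth$true_log10_ec50[hit] <- ov$true_log10_ec50[idx[hit]]
  }
  truth$non_responder <- truth$compound %in% params$non_responders
  truth$true_log10_ec50[truth$non_responder] <- NA_real_
  truth
}

#' Generate a synthetic multicenter dataset
#'
#' Produces well-level raw signals for every combination of design block,
#' run, endpoint, exposure time, compound, grid concentration and technical
#' triplicate, plus `n_vehicle` vehicle wells per block. The latent percent
#' viability of a treated well is
#' `true_top / (1 + c / EC50_eff)` with
#' `log10 EC50_eff = true_log10_ec50 + site + unit + run shift`
#' (+ the 24 h time shift); observed viability adds Gaussian noise truncated
#' at 0, and the raw signal is `viability/100 * vehicle mean * lognormal
#' vehicle noise`. Non-responder compounds are generated flat at `true_top`.
#'
#' @param panel Compound panel ([load_panel()]).
#' @param design Study design ([default_design()]).
#' @param params Generator parameters ([default_params()]).
#' @param seed Integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @return A list with `wells` (validated tibble, see [read_wells()]) and
#'   `truth` (ground-truth tables: `compound_truth`, `site_shifts`,
#'   `unit_shifts`, `run_shifts`, plus the `params` and `design` used).
#' @export
#' @examples
#' panel <- load_panel()
#' sc <- preset_scenarios(panel)$null_interlab
#' d <- generate_dataset(panel, sc$design, sc$params, seed = 1)
#' nrow(d$wells)
generate_dataset <- function(panel, design, params, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required: synthetic datasets must be reproducible",
         call. = FALSE)
  }
  stopifnot(nrow(design$blocks) > 0, design$n_vehicle >= 6)
  set.seed(as.integer(seed))

  truth <- truth_table(panel, design, params)

  sites <- sort(unique(design$blocks$site))
  units <- sort(unique(design$blocks$unit))
  site_shifts <- tibble::tibble(
    site = sites,
    shift = stats::rnorm(length(sites), 0, params$site_shift_sd))
  unit_shifts <- tibble::tibble(
    unit = units,
    shift = stats::rnorm(length(units), 0, params$unit_shift_sd))
  run_grid <- tidyr::expand_grid(design$blocks, run = seq_len(design$n_runs))
  run_shifts <- dplyr::mutate(
    run_grid,
    shift = stats::rnorm(nrow(run_grid), 0, params$run_shift_sd))

  # full treated factorial, in a fixed deterministic order
  treated <- tidyr::expand_grid(
    design$blocks,
    run = seq_len(design$n_runs),
    endpoint = design$endpoints,
    exposure_h = design$exposure_h,
    compound = panel$name)
  dose_tbl <- tibble::tibble(
    compound = rep(panel$name, each = 7L),
    concentration_um = unlist(panel$concentrations_um, use.names = FALSE))
  treated <- dplyr::inner_join(treated, dose_tbl, by = "compound",
                               relationship = "many-to-many")
  treated <- tidyr::expand_grid(treated, tech_rep = 1:3)

  treated <- dplyr::left_join(treated, truth,
                              by = c("compound", "cell_model"))
  treated <- dplyr::left_join(
    treated, dplyr::rename(site_shifts, site_shift = "shift"), by = "site")
  treated <- dplyr::left_join(
    treated, dplyr::rename(unit_shifts, unit_shift = "shift"), by = "unit")
  treated <- dplyr::left_join(
    treated, dplyr::rename(run_shifts, run_shift = "shift"),
    by = c("cell_model", "site", "unit", "run"))

  log_ec50_eff <- treated$true_log10_ec50 + treated$site_shift +
    treated$unit_shift + treated$run_shift +
    ifelse(treated$exposure_h == 24L, params$time_shift_log10, 0)
  latent <- ifelse(treated$non_responder,
                   treated$true_top,
                   treated$true_top /
                     (1 + treated$concentration_um / 10^log_ec50_eff))
  viability <- latent + stats::rnorm(nrow(treated), 0, params$noise_sd_pct)
  viability <- pmax(viability, 0)

  veh_mean <- vehicle_mean_for(params$vehicle_signal_mean, treated$endpoint)
  sdlog <- sqrt(log(1 + params$vehicle_cv^2))
  treated$signal <- viability / 100 * veh_mean *
    exp(stats::rnorm(nrow(treated), -sdlog^2 / 2, sdlog))

  vehicle <- tidyr::expand_grid(
    design$blocks,
    run = seq_len(design$n_runs),
    endpoint = design$endpoints,
    exposure_h = design$exposure_h,
    tech_rep_slot = seq_len(design$n_vehicle))
  vm <- vehicle_mean_for(params$vehicle_signal_mean, vehicle$endpoint)
  vehicle$signal <- vm * exp(stats::rnorm(nrow(vehicle), -sdlog^2 / 2, sdlog))
  vehicle$compound <- "vehicle"
  vehicle$concentration_um <- 0
  vehicle$tech_rep <- ((vehicle$tech_rep_slot - 1L) %% 3L) + 1L
  vehicle$run <- as.integer(vehicle$run)

  wells <- dplyr::bind_rows(
    treated[, well_columns()],
    vehicle[, well_columns()])
  wells$exposure_h <- as.integer(wells$exposure_h)
  wells$run <- as.integer(wells$run)
  wells$tech_rep <- as.integer(wells$tech_rep)
  wells <- validate_wells(wells)

  truth_out <- list(compound_truth = truth,
                    site_shifts = site_shifts,
                    unit_shifts = unit_shifts,
                    run_shifts = run_shifts,
                    params = params,
                    design = design)
  list(wells = wells, truth = truth_out)
}

vehicle_mean_for <- function(vehicle_signal_mean, endpoint) {
  if (length(vehicle_signal_mean) == 1L && is.null(names(vehicle_signal_mean))) {
    rep(vehicle_signal_mean, length(endpoint))
  } else {
    unname(vehicle_signal_mean[endpoint])
  }
}

#' Latent (noise-free) viability implied by the ground truth
#'
#' Recomputes, for each treated well, the deterministic percent viability the
#' generator used before adding well noise. Useful for checking that
#' normalization recovers the generating curve and for closed-form
#' concordance calculations.
#'
#' @param wells Treated well tibble (vehicle rows are dropped).
#' @param truth Truth list as returned by [generate_dataset()].
#' @return The treated wells with a `latent_viability_pct` column.
#' @export
latent_viability <- function(wells, truth) {
  tr <- wells[wells$compound != "vehicle", , drop = FALSE]
  tr <- dplyr::left_join(tr, truth$compound_truth,
                         by = c("compound", "cell_model"))
  tr <- dplyr::left_join(
    tr, dplyr::rename(truth$site_shifts, site_shift = "shift"), by = "site")
  tr <- dplyr::left_join(
    tr, dplyr::rename(truth$unit_shifts, unit_shift = "shift"), by = "unit")
  tr <- dplyr::left_join(
    tr, dplyr::rename(truth$run_shifts, run_shift = "shift"),
    by = c("cell_model", "site", "unit", "run"))
  log_ec50_eff <- tr$true_log10_ec50 + tr$site_shift + tr$unit_shift +
    tr$run_shift +
    ifelse(tr$exposure_h == 24L, truth$params$time_shift_log10, 0)
  tr$latent_viability_pct <- ifelse(
    tr$non_responder, tr$true_top,
    tr$true_top / (1 + tr$concentration_um / 10^log_ec50_eff))
  tr
}

#' Named preset simulation scenarios
#'
#' * `default` — the full multicenter design ([default_design()]) with 5 %
#'   well noise and 0.15 log10 between-site shifts; used for ground-truth
#'   recovery checks.
#' * `null_interlab` — two sites, one cell model, all site/unit/run shifts
#'   zero; the null configuration for F-test calibration.
#' * `phh_like` — a three-site primary-hepatocyte-like configuration whose
#'   true EC50s are placed so that at an EC50/Cmax threshold of 20 after 72 h
#'   exactly 8 of 9 DILI compounds (all but the flat non-responder) and 1 of
#'   4 non-DILI compounds classify as toxic. A pipeline-logic construction,
#'   not a fit to any experimental dataset.
#' * `clustered` — five donor columns sharing one cytotoxicity profile and
#'   three cell-line columns sharing a clearly different one; ground truth
#'   for hierarchical-clustering checks.
#' * `attenuation` — one block, both endpoints sharing the latent viability
#'   with independent well noise and near-noiseless vehicle wells; supports
#'   the closed-form Pearson attenuation check.
#'
#' @param panel Compound panel ([load_panel()]).
#' @return Named list of scenarios, each a list with `design` and `params`.
#' @export
preset_scenarios <- function(panel = load_panel()) {
  cmax <- stats::setNames(panel$cmax_um, panel$name)

  # phh_like: DILI compounds (minus the non-responder) at margin 5,
  # entacapone at margin 10, remaining non-DILI compounds well above 20.
  phh_ec50 <- c(amiodarone = 5 * cmax[["amiodarone"]],
                bosentan = 5 * cmax[["bosentan"]],
                diclofenac = 5 * cmax[["diclofenac"]],
                nefazodone = 5 * cmax[["nefazodone"]],
                paracetamol = 5 * cmax[["paracetamol"]],
                perhexiline = 5 * cmax[["perhexiline"]],
                tolcapone = 5 * cmax[["tolcapone"]],
                troglitazone = 5 * cmax[["troglitazone"]],
                ximelagatran = 30,  # ignored: non-responder
                buspirone = 50, entacapone = 15, metformin = 1000,
                pioglitazone = 150)

  phh_design <- list(
    blocks = tibble::tibble(cell_model = "PHH_cryo",
                            site = c("S1", "S2", "S3"), unit = "D_B17"),
    n_runs = 1L, endpoints = "ATP", exposure_h = c(24L, 72L),
    n_vehicle = 6L)
  phh_params <- default_params(panel)
  phh_params$base_log10_ec50 <- log10(phh_ec50[panel$name])
  names(phh_params$base_log10_ec50) <- panel$name
  phh_params$model_offset_log10 <- c(PHH_cryo = 0)
  phh_params$time_shift_log10 <- 0.8
  phh_params$site_shift_sd <- 0.1
  phh_params$unit_shift_sd <- 1e-6
  phh_params$run_shift_sd <- 1e-6

  null_design <- list(
    blocks = tibble::tibble(cell_model = "HepG2_ECACC",
                            site = c("S1", "S2"), unit = "ECACC"),
    n_runs = 1L, endpoints = "ATP", exposure_h = 72L, n_vehicle = 6L)
  null_params <- default_params(panel, non_responders = character(0))
  null_params$model_offset_log10 <- c(HepG2_ECACC = 0)
  null_params$site_shift_sd <- 1e-9
  null_params$unit_shift_sd <- 1e-9
  null_params$run_shift_sd <- 1e-9
  null_params$time_shift_log10 <- 0
  # under the null the two series must share one true curve after
  # normalization; near-noiseless vehicle wells keep block rescaling from
  # breaking that identity
  null_params$vehicle_cv <- 1e-6

  # clustered: donor columns share profile A, cell-line columns profile B;
  # alternating +/-0.6 log10 around the 4th grid dose keeps every EC50
  # within its tested range.
  clu_design <- list(
    blocks = dplyr::bind_rows(
      tibble::tibble(cell_model = "PHH_cryo", site = "S1",
                     unit = paste0("D", 1:5)),
      tibble::tibble(cell_model = c("HepG2_ECACC", "HepaRG_cryo", "Upcyte"),
                     site = "S1", unit = c("ECACC", "HPR116", "422A"))),
    n_runs = 1L, endpoints = "ATP", exposure_h = 72L, n_vehicle = 6L)
  clu_params <- default_params(panel, base_dose_index = 4L,
                               non_responders = character(0))
  sign_pat <- rep(c(-0.6, 0.6), length.out = nrow(panel))
  clu_truth <- dplyr::bind_rows(lapply(
    unique(clu_design$blocks$cell_model), function(m) {
      s <- if (m == "PHH_cryo") sign_pat else -sign_pat
      tibble::tibble(compound = panel$name, cell_model = m,
                     true_log10_ec50 = clu_params$base_log10_ec50 + s)
    }))
  clu_params$truth_log10_ec50 <- clu_truth
  clu_params$model_offset_log10 <- c(PHH_cryo = 0, HepG2_ECACC = 0,
                                     HepaRG_cryo = 0, Upcyte = 0)
  clu_params$site_shift_sd <- 1e-6
  clu_params$unit_shift_sd <- 0.05
  clu_params$run_shift_sd <- 1e-6
  clu_params$noise_sd_pct <- 3
  clu_params$time_shift_log10 <- 0

  att_design <- list(
    blocks = tibble::tibble(cell_model = "HepG2_ECACC", site = "S1",
                            unit = "ECACC"),
    n_runs = 1L, endpoints = c("ATP", "resorufin"), exposure_h = 72L,
    n_vehicle = 6L)
  att_params <- default_params(panel, base_dose_index = 6L,
                               non_responders = character(0))
  att_params$model_offset_log10 <- c(HepG2_ECACC = 0)
  att_params$site_shift_sd <- 1e-9
  att_params$unit_shift_sd <- 1e-9
  att_params$run_shift_sd <- 1e-9
  att_params$time_shift_log10 <- 0
  att_params$vehicle_cv <- 0.001

  list(
    default = list(design = default_design(),
                   params = default_params(panel)),
    null_interlab = list(design = null_design, params = null_params),
    phh_like = list(design = phh_design, params = phh_params),
    clustered = list(design = clu_design, params = clu_params),
    attenuation = list(design = att_design, params = att_params))
}

#' Ground-truth recovery errors
#'
#' Joins fitted series to the generator's truth table and summarizes, per
#' responsive `(compound, cell_model, endpoint, exposure_h)` cell, the
#' absolute log10 error of the estimated EC50 (series estimates averaged on
#' the log10 scale). The 24 h time shift of the truth is accounted for.
#'
#' @param fits Output of [fit_all()] on a synthetic dataset.
#' @param truth Truth list from [generate_dataset()].
#' @return Tibble with the cell key, `true_log10_ec50` (time-adjusted),
#'   `est_log10_ec50`, `n_fit`, `n_series` and `abs_log10_error` (NA where
#'   no series fitted).
#' @export
recovery_errors <- function(fits, truth) {
  merged <- dplyr::inner_join(fits, truth$compound_truth,
                              by = c("compound", "cell_model"))
  merged <- merged[!merged$non_responder, , drop = FALSE]
  merged$true_adj <- merged$true_log10_ec50 +
    ifelse(merged$exposure_h == 24L, truth$params$time_shift_log10, 0)
  grouped <- dplyr::group_by(merged, .data$compound, .data$cell_model,
                             .data$endpoint, .data$exposure_h)
  out <- dplyr::summarise(
    grouped,
    true_log10_ec50 = .data$true_adj[1],
    n_series = dplyr::n(),
    n_fit = sum(.data$status == "fit"),
    est_log10_ec50 = ifelse(sum(.data$status == "fit") > 0,
                            mean(.data$log10_ec50[.data$status == "fit"]),
                            NA_real_),
    .groups = "drop")
  out$abs_log10_error <- abs(out$est_log10_ec50 - out$true_log10_ec50)
  out
}
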