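panel <- load_panel()

test_that("the generator is deterministic under a fixed seed and requires one", {
  sc <- preset_scenarios(panel)$null_interlab
  d1 <- generate_dataset(panel, sc$design, sc$params, seed = 5)
  d2 <- generate_dataset(panel, sc$design, sc$params, seed = 5)
  expect_identical(d1$wells, d2$wells)
  expect_identical(d1$truth$site_shifts, d2$truth$site_shifts)
  d3 <- generate_dataset(panel, sc$design, sc$params, seed = 6)
  expect_false(identical(d1$wells$signal, d3$wells$signal))
  expect_error(generate_dataset(panel, sc$design, sc$params),
               "seed is required")
})

test_that("generated wells cover the full factorial plus vehicle blocks", {
  sc <- preset_scenarios(panel)$null_interlab
  wells <- generate_dataset(panel, sc$design, sc$params, seed = 2)$wells
  treated <- wells[wells$compound != "vehicle", ]
  # 2 sites x 13 compounds x 7 doses x 3 reps
  expect_equal(nrow(treated), 2 * 13 * 7 * 3)
  counts <- table(treated$compound, treated$site)
  expect_true(all(counts == 21))
  veh <- wells[wells$compound == "vehicle", ]
  veh_blocks <- dplyr::count(veh, cell_model, site, unit, endpoint,
                             exposure_h, run)
  expect_true(all(veh_blocks$n >= 6))
  expect_true(all(veh$concentration_um == 0))
})

test_that("noiseless, shift-free data are recovered exactly by the fit", {
  sc <- preset_scenarios(panel)$null_interlab
  sc$params$noise_sd_pct <- 1e-9
  sc$params$vehicle_cv <- 1e-9
  d <- generate_dataset(panel, sc$design, sc$params, seed = 3)
  fits <- fit_all(normalize_to_vehicle(d$wells))
  truth <- d$truth$compound_truth
  merged <- dplyr::inner_join(fits, truth, by = c("compound", "cell_model"))
  responsive <- merged[!merged$non_responder, ]
  expect_true(all(responsive$status == "fit"))
  expect_lt(max(abs(responsive$log10_ec50 - responsive$true_log10_ec50)),
            1e-4)
  expect_lt(max(abs(responsive$top - 100)), 1e-2)
})

test_that("non-responder compounds yield no_fit in every downstream series", {
  sc <- preset_scenarios(panel)$default
  sc$design$n_runs <- 1L
  sc$design$endpoints <- "ATP"
  sc$design$exposure_h <- 72L
  d <- generate_dataset(panel, sc$design, sc$params, seed = 4)
  fits <- fit_all(normalize_to_vehicle(d$wells))
  xim <- fits[fits$compound == "ximelagatran", ]
  expect_gt(nrow(xim), 0)
  expect_true(all(xim$status == "no_fit"))
})

test_that("expected viability near zero dose equals the true top", {
  sc <- preset_scenarios(panel)$attenuation
  d <- generate_dataset(panel, sc$design, sc$params, seed = 9)
  series <- normalize_to_vehicle(d$wells)
  lowest <- dplyr::group_by(series, compound)
  lowest <- dplyr::filter(lowest,
                          concentration_um == min(concentration_um))
  lat <- latent_viability(d$wells, d$truth)
  low_lat <- lat[lat$concentration_um ==
                   ave(lat$concentration_um, lat$compound, FUN = min), ]
  # latent at the lowest dose is close to top (EC50 sits at the 6th dose)
  expect_true(all(low_lat$latent_viability_pct > 90))
  # observed viability centers on the latent value
  expect_lt(abs(mean(lowest$viability_pct) -
                  mean(low_lat$latent_viability_pct)), 2)
})

test_that("normalization recovers the generator's latent viabilities", {
  sc <- preset_scenarios(panel)$attenuation
  d <- generate_dataset(panel, sc$design, sc$params, seed = 12)
  series <- normalize_to_vehicle(d$wells)
  lat <- latent_viability(d$wells, d$truth)
  key <- c("compound", "endpoint", "concentration_um", "tech_rep")
  merged <- dplyr::inner_join(series, lat[, c(key, "latent_viability_pct")],
                              by = key)
  resid <- merged$viability_pct - merged$latent_viability_pct
  # residuals are the injected 5 % Gaussian well noise
  expect_lt(abs(mean(resid)), 1)
  expect_lt(abs(sd(resid) - sc$params$noise_sd_pct), 1.5)
})
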