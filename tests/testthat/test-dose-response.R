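panel <- load_panel()

test_that("normalization divides by the block vehicle mean", {
  wells <- tibble::tibble(
    cell_model = "HepG2_ECACC", site = "S1", unit = "ECACC",
    compound = c(rep("vehicle", 3), rep("amiodarone", 7)),
    endpoint = "ATP", exposure_h = 24L,
    concentration_um = c(0, 0, 0, 3, 5, 10, 30, 50, 100, 300),
    run = 1L, tech_rep = 1L,
    signal = c(10000, 10000, 10000, 10000, 9000, 8000, 5000, 2500, 1000, 250))
  series <- normalize_to_vehicle(wells)
  expect_equal(series$viability_pct[series$concentration_um == 3], 100)
  expect_equal(series$viability_pct[series$concentration_um == 50], 25)
})

test_that("a block without vehicle wells halts normalization, naming it", {
  wells <- tibble::tibble(
    cell_model = "HepG2_ECACC", site = "S1", unit = "ECACC",
    compound = "amiodarone", endpoint = "ATP", exposure_h = 24L,
    concentration_um = c(3, 5, 10, 30, 50, 100, 300), run = 1L,
    tech_rep = 1L, signal = 1000)
  expect_error(normalize_to_vehicle(wells), "vehicle wells")
  expect_error(normalize_to_vehicle(wells), "HepG2_ECACC/S1/ECACC")
})

test_that("noiseless model points are recovered exactly", {
  cc <- rep(c(3, 5, 10, 30, 50, 100, 300), each = 3)
  v <- 100 * 50 / (50 + cc)
  f <- fit_series(cc, v)
  expect_equal(f$log10_ec50, log10(50), tolerance = 1e-6)
  expect_equal(f$top, 100, tolerance = 1e-4)
  expect_lt(f$rss, 1e-8)
  expect_equal(f$df, length(cc) - 2L)
  expect_identical(f$status, "fit")
  # fixing Top costs one parameter
  f2 <- fit_series(cc, v, fit_options(fix_top = 100))
  expect_equal(f2$df, length(cc) - 1L)
  expect_equal(f2$log10_ec50, log10(50), tolerance = 1e-6)
})

test_that("the no-fit rule fires on flat, shallow and out-of-range series", {
  grid <- c(3, 5, 10, 30, 50, 100, 300)
  cc <- rep(grid, each = 3)
  # (b) flat at 100 %: no decrease in viability
  flat <- fit_series(cc, rep(100, length(cc)))
  expect_identical(flat$status, "no_fit")
  # (b)+(c) noiseless series from EC50 = 10 x max dose declines only to ~91 %
  v <- 100 / (1 + cc / (10 * max(grid)))
  shallow <- fit_series(cc, v)
  expect_identical(shallow$status, "no_fit")
  expect_gt(mean(v[cc == max(grid)]), 80)
  expect_gt(shallow$ec50_um, max(grid))
  # clear responder crossing 50 % mid-grid
  resp <- fit_series(cc, 100 / (1 + cc / 30))
  expect_identical(resp$status, "fit")
})

test_that("optimizer matches the exhaustive grid-search oracle", {
  set.seed(42)
  for (i in 1:5) {
    s <- make_series(ec50 = 10^runif(1, 0.8, 2.2),
                     top = runif(1, 90, 110), noise = 5)
    f <- fit_series(s$concentration_um, s$viability_pct)
    oracle <- grid_fit_oracle(s$concentration_um, s$viability_pct)
    expect_lte(f$rss, oracle$rss * (1 + 1e-6))
    expect_lt(abs(f$log10_ec50 - oracle$log10_ec50), 0.02)
  }
})

test_that("fitting is equivariant under concentration rescaling", {
  set.seed(7)
  s <- make_series(ec50 = 40, noise = 4)
  f1 <- fit_series(s$concentration_um, s$viability_pct)
  for (k in c(10, 0.1, 3.7)) {
    f2 <- fit_series(s$concentration_um * k, s$viability_pct)
    expect_equal(f2$log10_ec50, f1$log10_ec50 + log10(k), tolerance = 1e-4)
    expect_equal(f2$rss, f1$rss, tolerance = 1e-6)
  }
})

test_that("residual sum is invariant to point order and the model monotone", {
  set.seed(8)
  s <- make_series(ec50 = 25)
  idx <- sample(nrow(s))
  f1 <- fit_series(s$concentration_um, s$viability_pct)
  f2 <- fit_series(s$concentration_um[idx], s$viability_pct[idx])
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
  expect_equal(f1$log10_ec50, f2$log10_ec50, tolerance = 1e-8)
  cgrid <- sort(unique(s$concentration_um))
  pred <- f1$top / (1 + cgrid / f1$ec50_um)
  expect_true(all(diff(pred) < 0))
})

test_that("fit_series enforces its preconditions", {
  expect_error(fit_series(c(1, 2, 3, 4), c(90, 80, 60, 40)),
               "5 distinct concentrations")
  expect_error(fit_series(c(-1, 2, 3, 4, 5), c(90, 80, 60, 40, 20)),
               "positive concentrations")
})
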