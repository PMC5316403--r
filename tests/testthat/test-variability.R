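# A minimal fits table carrying only the key columns enumerate_pairs needs.
fit_stub <- function(cell_model, site, unit, compound = "amiodarone",
                     endpoint = "ATP", exposure_h = 72L, run = 1L) {
  tidyr::expand_grid(cell_model = cell_model, site = site, unit = unit,
                     compound = compound, endpoint = endpoint,
                     exposure_h = exposure_h, run = run)
}

test_that("inter-lab pairs are all site pairs within a stratum group", {
  fits <- fit_stub("HepG2_ECACC", c("S1", "S2", "S3"), "ECACC")
  pairs <- enumerate_pairs(fits, "inter_lab")
  expect_equal(nrow(pairs), choose(3, 2))
  fits2 <- fit_stub("HepG2_ECACC", c("S1", "S2", "S3"), "ECACC",
                    compound = c("amiodarone", "bosentan"))
  expect_equal(nrow(enumerate_pairs(fits2, "inter_lab")), 2 * 3)
})

test_that("inter-donor pairs count C(n_donors, 2) per compound/time", {
  fits <- fit_stub("PHH_cryo", "S1", paste0("D", 1:5))
  expect_equal(nrow(enumerate_pairs(fits, "inter_donor")), choose(5, 2))
  # donors at different sites still pair (allocation spreads donors)
  fits2 <- dplyr::bind_rows(fit_stub("PHH_cryo", "S1", c("D1", "D2")),
                            fit_stub("PHH_cryo", "S2", "D3"))
  expect_equal(nrow(enumerate_pairs(fits2, "inter_donor")), 3)
})

test_that("hand-enumerated pair list on a 2-site, 2-compound fixture matches", {
  fits <- fit_stub("Upcyte", c("S1", "S2"), "422A",
                   compound = c("amiodarone", "bosentan"))
  pairs <- enumerate_pairs(fits, "inter_lab")
  expected <- tibble::tibble(
    key_a = c("Upcyte|S1|422A|amiodarone|ATP|72|1",
              "Upcyte|S1|422A|bosentan|ATP|72|1"),
    key_b = c("Upcyte|S2|422A|amiodarone|ATP|72|1",
              "Upcyte|S2|422A|bosentan|ATP|72|1"))
  expect_equal(pairs[order(pairs$key_a), c("key_a", "key_b")], expected,
               ignore_attr = TRUE)
})

test_that("clone and fresh-vs-cryo strata pair across variants only", {
  fits <- fit_stub(c("HepG2_ECACC", "HepG2_TS"), "S1",
                   c("ECACC", "TS"))
  clone_pairs <- enumerate_pairs(fits[c(1, 4), ], "clone")
  expect_equal(nrow(clone_pairs), 1)
  fits2 <- dplyr::bind_rows(
    fit_stub("HepaRG_cryo", c("S1", "S2"), "HPR116"),
    fit_stub("HepaRG_fresh", "S1", "HPR116"))
  fc <- enumerate_pairs(fits2, "fresh_vs_cryo")
  # fresh series pairs with each cryo series, never cryo-with-cryo
  expect_equal(nrow(fc), 2)
  run_pairs <- enumerate_pairs(
    fit_stub("Upcyte", "S1", "422A", run = c(1L, 2L, 3L)), "intra_lab")
  expect_equal(nrow(run_pairs), choose(3, 2))
})

test_that("an under-populated stratum warns and returns no pairs", {
  fits <- fit_stub("Upcyte", "S1", "422A")
  expect_warning(pairs <- enumerate_pairs(fits, "inter_lab"),
                 "fewer than 2")
  expect_equal(nrow(pairs), 0)
})

test_that("variability coefficients follow the verbatim proportion", {
  cmp <- tibble::tibble(verdict = c("different", "different",
                                    rep("not_different", 4)))
  rep1 <- variability_coefficient(cmp)
  expect_equal(rep1$coefficient, 2 / 6)
  expect_equal(rep1$n_total,
               rep1$n_different + rep1$n_not_different + rep1$n_no_fit)

  all_nd <- variability_coefficient(
    tibble::tibble(verdict = rep("not_different", 5)))
  expect_equal(all_nd$coefficient, 0)

  mixed <- variability_coefficient(tibble::tibble(
    verdict = c("different", "not_different", "not_different", "no_fit")))
  expect_equal(mixed$coefficient, 0.25)  # no-fit stays in the denominator
  expect_equal(mixed$n_no_fit, 1)

  # invariant to permutation of the comparison list
  perm <- variability_coefficient(cmp[sample(nrow(cmp)), , drop = FALSE])
  expect_equal(perm$coefficient, rep1$coefficient)

  expect_error(variability_coefficient(tibble::tibble(verdict = character(0))),
               "zero comparisons")
})
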