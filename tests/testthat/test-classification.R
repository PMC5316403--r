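panel <- load_panel()

ec50_row <- function(compound, ec50_um, status = "fit") {
  tibble::tibble(compound = compound,
                 log10_ec50 = ifelse(is.na(ec50_um), NA_real_,
                                     log10(ec50_um)),
                 ec50_um = ec50_um, status = status)
}

test_that("margins are EC50/Cmax on the micromolar scale", {
  m <- compute_margins(ec50_row("amiodarone", 16.14), panel)
  expect_equal(m$margin, 20.0, tolerance = 1e-3)
  m2 <- compute_margins(ec50_row("buspirone", 100), panel)
  expect_equal(m2$margin, 20000)
  expect_false(classify_margins(m2, 20)$classified_toxic)
  # margins scale linearly with the EC50
  expect_equal(compute_margins(ec50_row("bosentan", 74), panel)$margin,
               2 * compute_margins(ec50_row("bosentan", 37), panel)$margin)
  expect_error(compute_margins(ec50_row("novel_compound", 5), panel),
               "missing from the panel")
})

test_that("no-fit compounds carry no margin and are never called toxic", {
  m <- classify_margins(
    compute_margins(ec50_row("ximelagatran", NA_real_, "no_fit"), panel), 20)
  expect_true(is.na(m$margin))
  expect_true(is.na(m$classified_toxic))
})

test_that("classification is strict at the threshold, idempotent and pure", {
  at20 <- compute_margins(ec50_row("amiodarone", 20 * 0.807), panel)
  expect_false(classify_margins(at20, 20)$classified_toxic)
  below <- compute_margins(ec50_row("amiodarone", 12.4 * 0.807), panel)
  expect_true(classify_margins(below, 20)$classified_toxic)
  twice <- classify_margins(classify_margins(below, 20), 20)
  expect_identical(twice$classified_toxic,
                   classify_margins(below, 20)$classified_toxic)
  expect_error(classify_margins(below, -1), "positive")
})

test_that("threshold sweep matches a brute-force recount and is monotone", {
  set.seed(14)
  margins <- compute_margins(
    ec50_row(panel$name, exp(runif(13, log(0.5), log(5000)))), panel)
  margins$status[margins$compound == "ximelagatran"] <- "no_fit"
  margins$margin[margins$compound == "ximelagatran"] <- NA
  grid <- c(0.001, 1, 2, 5, 10, 20, 50, 100, 1e6)
  sweep <- threshold_sweep(margins, grid)
  for (i in seq_along(grid)) {
    flagged <- !is.na(margins$margin) & margins$margin < grid[i]
    expect_equal(sweep$n_dili_flagged[i],
                 sum(flagged & margins$dili_label == "DILI"))
    expect_equal(sweep$n_nondili_flagged[i],
                 sum(flagged & margins$dili_label == "non-DILI"))
    expect_equal(sweep$sensitivity[i], sweep$n_dili_flagged[i] / 9)
    expect_equal(sweep$specificity[i],
                 (4 - sweep$n_nondili_flagged[i]) / 4)
  }
  expect_true(all(diff(sweep$n_dili_flagged) >= 0))
  expect_true(all(diff(sweep$n_nondili_flagged) >= 0))
  # limits: everything fitted flagged at infinity, nothing near zero
  expect_equal(sweep$sensitivity[length(grid)], 8 / 9)  # no-fit never flagged
  expect_equal(sweep$specificity[1], 1)
  expect_equal(sweep$sensitivity[1], 0)
})

test_that("separation check agrees with exhaustive cutoff search", {
  sep <- separation_check(compute_margins(
    ec50_row(panel$name, c(1, 5, 50, 100, 60, 70, 2, 3, 4, 80, 5, 6, 90)),
    panel))
  # brute force: try every threshold between sorted adjacent values
  brute_separable <- function(ec50s) {
    v <- ec50s$log10_ec50
    v[is.na(v)] <- max(v, na.rm = TRUE) + 1
    cuts <- sort(unique(v))
    any(vapply(cuts, function(ct) {
      all(v[ec50s$dili_label == "DILI"] <= ct) &&
        all(v[ec50s$dili_label == "non-DILI"] > ct)
    }, logical(1)))
  }
  m <- compute_margins(
    ec50_row(panel$name, c(1, 5, 50, 100, 60, 70, 2, 3, 4, 80, 5, 6, 90)),
    panel)
  expect_identical(sep$separable, brute_separable(m))

  # a separable construction: all DILI potent, all non-DILI weak
  ec <- ifelse(panel$dili_label == "DILI", 2, 500)
  msep <- compute_margins(ec50_row(panel$name, ec), panel)
  s2 <- separation_check(msep)
  expect_true(s2$separable)
  expect_identical(s2$separable, brute_separable(msep))
  expect_equal(s2$n_inversions, 0)
  expect_equal(s2$n_pairs, 9 * 4)
})
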