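# Formula arithmetic, ion masses, isotope patterns, subformula enumeration.

test_that("formula parsing reads multiplier pairs and round-trips", {
  expect_equal(parse_formula("C8H6O4"), c(C = 8L, H = 6L, O = 4L))
  expect_equal(parse_formula("C4H4ClN3O"),
               c(C = 4L, H = 4L, Cl = 1L, N = 3L, O = 1L))
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C2Xx4"), "unknown element")
  set.seed(11)
  for (i in 1:25) {
    f <- random_formula()
    back <- parse_formula(format_formula(f))
    expect_equal(back[sort(names(back))], f[sort(names(f))])
  }
})

test_that("monoisotopic masses match hand-summed values", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C8H6O4"), 166.026609, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(stats::setNames(integer(0), character(0))), 0)
})

test_that("ion m/z agrees with the independent mass-table oracle", {
  set.seed(21)
  for (i in 1:100) {
    f <- random_formula()
    ch <- sample(c(-1L, 1L), 1)
    expect_lt(abs(ion_mz(f, charge = ch) - oracle_ion_mz(f, ch)), 1e-5)
  }
})

test_that("proton-difference identity holds for neutral molecules", {
  set.seed(31)
  for (i in 1:20) {
    f <- random_formula()
    expect_equal(ion_mz(f, adduct = "[M+H]+") - ion_mz(f, adduct = "[M-H]-"),
                 2 * 1.00727646, tolerance = 1e-9)
  }
  expect_error(ion_mz("C6H6"), "exactly one")
  expect_error(ion_mz("C6H6", adduct = "[M+Na]+"), "unsupported adduct")
  expect_error(ion_mz("C6H6", charge = 2), "singly charged")
})

test_that("isotope patterns carry the chlorine A+2 signature", {
  p1 <- simulate_isotope_pattern("C3H2ClN2")
  expect_equal(p1$abundance[p1$offset == 2] / p1$abundance[1], 0.32,
               tolerance = 0.01 / 0.32)
  p2 <- simulate_isotope_pattern("C8H5Cl2O")
  expect_equal(p2$abundance[p2$offset == 2] / p2$abundance[1], 0.64,
               tolerance = 0.02 / 0.64)
  p0 <- simulate_isotope_pattern("C5H12")
  expect_lt(p0$abundance[p0$offset == 2] / p0$abundance[1], 0.01)
  # structure invariants
  expect_equal(p1$offset[1], 0)
  expect_equal(p1$abundance[1], 1)
  expect_true(all(p1$abundance >= 0))
})

test_that("A+2/A increases monotonically with chlorine count", {
  base <- c(C = 9L, H = 10L, N = 2L, O = 2L)
  ratios <- vapply(0:3, function(k) {
    f <- base
    if (k > 0) f["Cl"] <- k
    p <- simulate_isotope_pattern(f)
    p$abundance[p$offset == 2] / p$abundance[1]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("chlorine counting recovers 0-3 Cl and flags ambiguity", {
  expect_equal(estimate_chlorine_count(
    isotope_pattern(c(0, 1, 2), c(1, 0.1, 0.32)))$count, 1L)
  expect_equal(estimate_chlorine_count(
    isotope_pattern(c(0, 1, 2), c(1, 0.1, 0.64)))$count, 2L)
  expect_equal(estimate_chlorine_count(isotope_pattern(0, 1))$count, 0L)
  # halfway between 0 and 1 Cl: ambiguous
  amb <- estimate_chlorine_count(isotope_pattern(c(0, 2), c(1, 0.16)),
                                 tolerance = 0.2)
  expect_true(amb$low_confidence)
})

test_that("subformula enumeration is exhaustive, bounded and sorted", {
  hits <- enumerate_subformulas("C15H18Cl2N3O2", 87.04406, charge = 1,
                                tol_ppm = 5)
  expect_true("C4H7O2" %in% hits$formula)
  expect_true(all(diff(abs(hits$error_ppm)) >= 0))
  hits2 <- enumerate_subformulas("C4H5ClN3O", 100.99010, charge = 1,
                                 tol_ppm = 5)
  expect_true("C3H2ClN2" %in% hits2$formula)
  # a target above the precursor ion mass cannot match
  pre_mz <- ion_mz("C4H5ClN3O", charge = 1)
  expect_equal(nrow(enumerate_subformulas("C4H5ClN3O", pre_mz + 1,
                                          charge = 1)), 0)
})

test_that("enumeration equals the nested-loop brute force", {
  set.seed(41)
  for (i in 1:8) {
    bounds <- random_formula(max_c = 12)
    bounds <- bounds[cumsum(bounds) <= 40]   # keep precursors modest
    pre_mz <- oracle_ion_mz(bounds, 1)
    target <- runif(1, 50, pre_mz)
    got <- enumerate_subformulas(bounds, target, charge = 1, tol_ppm = 20)
    want <- oracle_subformulas(bounds, target, 1, 20)
    expect_setequal(got$formula, unname(want))
  }
})
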