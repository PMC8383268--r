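# Exact-mass matching, peak-quality gate, RT plausibility, fragment scoring.

gaussian_trace <- function(n = 20, height = 1000, snr = Inf, width = 0.1,
                           rt = 5, asym = 1) {
  t <- seq(rt - 3 * width, rt + 3 * width * asym, length.out = n)
  sigma <- ifelse(t < rt, width, width * asym)
  y <- height * exp(-(t - rt)^2 / (2 * sigma^2))
  if (is.finite(snr)) y <- pmax(0, y + rnorm(n, 0, height / snr))
  cbind(t, y)
}

test_that("suspect matching respects the ppm window and polarity", {
  fx <- make_registry_fixture(2, 0, 2, 0)
  sus <- build_suspect_list(fx$registry, fx$metabolites)
  tp <- sus[sus$origin == "key_metabolite", ][1, ]
  mk_feature <- function(mz, polarity) {
    f <- data.frame(feature_id = "F1", site = "E", week = "2017-05-01",
                    polarity = polarity, mz = mz, rt = 5, area = 1e5,
                    stringsAsFactors = FALSE)
    f$trace <- list(gaussian_trace())
    f$isotope <- list(cbind(0, 1))
    f$ms2 <- list(matrix(numeric(0), ncol = 2))
    f
  }
  hit <- match_suspects(mk_feature(tp$mz_pos * (1 + 0.5e-6), "positive"), sus)
  expect_equal(hit$suspect_id, tp$suspect_id)
  expect_lt(abs(hit$mass_error_ppm), 1)
  # same m/z in the wrong polarity does not match this suspect
  miss <- match_suspects(mk_feature(tp$mz_pos * (1 + 0.5e-6), "negative"), sus)
  expect_false(tp$suspect_id %in% miss$suspect_id)
  # 10 ppm off with a 5 ppm window: no hit
  expect_equal(nrow(match_suspects(mk_feature(tp$mz_pos * (1 + 10e-6),
                                              "positive"), sus)), 0)
  expect_equal(nrow(match_suspects(mk_feature(1, "positive")[0, ], sus)), 0)
})

test_that("a known spiked feature matches within 1 ppm of theory", {
  # desphenyl-type TP formula; protonated theory from an independent oracle
  mz_theory <- oracle_ion_mz(c(C = 4L, H = 5L, Cl = 1L, N = 3L, O = 1L), 1)
  expect_equal(ion_mz("C4H4ClN3O", adduct = "[M+H]+"), mz_theory,
               tolerance = 1e-6)
  expect_equal(round(mz_theory, 5), 146.01155, tolerance = 2e-5)
})

test_that("peak-quality gate enforces points, symmetry and SNR", {
  set.seed(61)
  good <- assess_peak_quality(gaussian_trace(n = 20, snr = 50))
  expect_true(good$pass)
  expect_gt(good$score, 0.5)
  spike <- assess_peak_quality(cbind(1:3, c(0, 100, 0)))
  expect_false(spike$pass)
  flat <- assess_peak_quality(cbind(1:10, rep(0, 10)))
  expect_false(flat$pass)
  expect_equal(flat$score, 0)
  skewed <- assess_peak_quality(gaussian_trace(n = 40, snr = 100, asym = 4))
  expect_false(skewed$pass)
  # SNR criterion: a trace whose noise dwarfs the required ratio fails
  noisy <- assess_peak_quality(gaussian_trace(n = 20, snr = 2), min_snr = 10)
  expect_false(noisy$pass)
})

test_that("RT model fits a line and flags implausible retention", {
  d <- 1:10
  rt <- 2 + 1.5 * d + rnorm(10, 0, 1e-8)
  m <- fit_rt_model(d, rt)
  expect_equal(m$slope, 1.5, tolerance = 1e-4)
  expect_equal(rt_plausible(2 + 1.5 * 4, 4, m), "pass")
  expect_equal(rt_plausible(2 + 1.5 * 4 + 10 * m$residual_spread, 4, m),
               "fail")
  expect_equal(rt_plausible(5, NA, m), "unknown")
  expect_error(fit_rt_model(1:3, 1:3), "calibrants")
})

test_that("fragment scoring counts diagnostics and grades the tier", {
  rec <- list(name = "chloridazon-TP1-like", formula = "C4H4ClN3O",
              adduct = "[M+H]+", precursor_mz = 146.01155,
              peaks = cbind(c(100.99010, 116.99759), c(100, 80)),
              diagnostic = c(TRUE, TRUE), warning = "")
  ms2 <- cbind(c(100.99010, 116.99759), c(500, 400))
  sc <- score_fragments(ms2, rec, "C4H4ClN3O", "positive")
  expect_equal(sc$n_diagnostic_matched, 2L)
  expect_equal(sc$n_library_matched, 2L)
  expect_equal(sc$chem_evidence_tier, "strong")
  # empty spectrum: weak, zero counts
  sc0 <- score_fragments(matrix(numeric(0), ncol = 2), rec, "C4H4ClN3O",
                         "positive")
  expect_equal(sc0$chem_evidence_tier, "weak")
  expect_equal(sc0$n_library_matched, 0L)
  # a fragment heavier than the precursor has no subformula: implausible
  heavy <- cbind(c(100.99010, 300.5), c(100, 100))
  sch <- score_fragments(heavy, rec, "C4H4ClN3O", "positive")
  expect_equal(sch$subformula_plausible_fraction, 0.5)
  # one diagnostic match with plausible spectrum: moderate
  one <- cbind(100.99010, 100)
  sc1 <- score_fragments(one, rec, "C4H4ClN3O", "positive")
  expect_equal(sc1$n_diagnostic_matched, 1L)
  expect_equal(sc1$chem_evidence_tier, "moderate")
})

test_that("gate cascade is monotone on a synthetic scenario", {
  sc <- generate_scenario(small_scenario_config(301), withr::local_tempdir())
  res <- run_pipeline(file.path(dirname(sc$paths$registry), "config.json"))
  cnt <- res$counts
  expect_lte(cnt$after_peak_rt, cnt$matched)
  expect_lte(cnt$after_fragments, cnt$after_peak_rt)
  expect_lte(cnt$retained, cnt$after_fragments)
  expect_lte(cnt$unique, cnt$retained)
})

test_that("spiked TPs with library records and high SNR reach tier strong", {
  cfg <- small_scenario_config(302)
  sc <- generate_scenario(cfg, withr::local_tempdir())
  res <- run_pipeline(file.path(dirname(sc$paths$registry), "config.json"))
  with_lib <- sc$truth$suspect_id[sc$truth$has_library]
  cand <- res$candidates
  for (id in with_lib) {
    expect_true(any(cand$suspect_id == id & cand$tier == "strong"),
                label = paste("strong tier for", id))
  }
})
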