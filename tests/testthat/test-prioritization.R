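# Monitoring evidence, retention, confidence levels, confirmation, dedup.

mk_suspect <- function(id = "TP1", parents = "P001", k_foc = NA_real_) {
  data.frame(suspect_id = id, name = id, formula = "C4H4ClN3O",
             neutral_mass = 145, mz_pos = 146, mz_neg = 144,
             origin = "key_metabolite", parent_ids = parents, k_foc = k_foc,
             stringsAsFactors = FALSE)
}

mk_registry <- function(sites = "E;M") {
  data.frame(compound_id = "P001", name = "parent", formula = "C10H12NO2",
             role = "monitored_target", addition_category = NA_character_,
             registered_sites = sites, stringsAsFactors = FALSE)
}

no_apps <- data.frame(site = character(0), date = character(0),
                      compound_id = character(0), dose = numeric(0))
no_dets <- data.frame(site = character(0), week = character(0),
                      compound_id = character(0), concentration = numeric(0))

test_that("evidence captures old applications within the lookback window", {
  apps <- data.frame(site = "M", date = "2014-05-15", compound_id = "P001",
                     dose = 100, stringsAsFactors = FALSE)
  dets <- data.frame(site = "M", week = "2017-06-05", compound_id = "P001",
                     concentration = 0.2, stringsAsFactors = FALSE)
  ev <- collect_monitoring_evidence(mk_suspect(), "M", mk_registry(),
                                    apps, dets, at_date = "2017-09-25")
  expect_true(ev$parent_applied_at_site)
  expect_true(ev$parent_detected_at_site)
  expect_equal(ev$last_application_date, as.Date("2014-05-15"))
  expect_equal(ev$source_plausibility, "supported")
  # same application falls outside a 2-year lookback
  ev2 <- collect_monitoring_evidence(mk_suspect(), "M", mk_registry(),
                                     apps, dets, at_date = "2017-09-25",
                                     lookback_years = 2)
  expect_false(ev2$parent_applied_at_site)
})

test_that("a parent with no registration, use or detection contradicts", {
  ev <- collect_monitoring_evidence(mk_suspect(), "E", mk_registry(sites = ""),
                                    no_apps, no_dets, at_date = "2017-09-25")
  expect_equal(ev$source_plausibility, "contradicted")
  # registered elsewhere only: neutral at this site
  ev2 <- collect_monitoring_evidence(mk_suspect(), "E", mk_registry("M"),
                                     no_apps, no_dets,
                                     at_date = "2017-09-25")
  expect_equal(ev2$source_plausibility, "neutral")
})

test_that("mobility flag compares TP and parent K_foc when both exist", {
  mets <- data.frame(parent_id = "P001", tp_id = "TP1", tp_name = "TP1",
                     formula = "C4H4ClN3O", k_foc = 242,
                     parent_k_foc = 186000, stringsAsFactors = FALSE)
  ev <- collect_monitoring_evidence(mk_suspect(k_foc = 242), "E",
                                    mk_registry(), no_apps, no_dets,
                                    at_date = "2017-09-25",
                                    metabolites = mets)
  expect_true(ev$mobility_flag)
  ev2 <- collect_monitoring_evidence(mk_suspect(), "E", mk_registry(),
                                     no_apps, no_dets,
                                     at_date = "2017-09-25")
  expect_true(is.na(ev2$mobility_flag))
})

test_that("retention keeps chemistry and rescues monitoring-supported hits", {
  supported <- structure(list(parent_registered_at_site = FALSE,
                              parent_applied_at_site = TRUE,
                              last_application_date = as.Date("2014-05-15"),
                              parent_detected_at_site = FALSE,
                              parent_detection_weeks = as.Date(character(0)),
                              mobility_flag = NA,
                              source_plausibility = "supported"),
                         class = "monitoring_evidence")
  unsupported <- supported
  unsupported$parent_applied_at_site <- FALSE
  unsupported$source_plausibility <- "neutral"
  contradicted <- unsupported
  contradicted$source_plausibility <- "contradicted"

  expect_equal(decide_retention("strong", unsupported)$decision, "retain")
  r <- decide_retention("weak", supported)
  expect_equal(r$decision, "retain")
  expect_equal(r$rationale, "monitoring_rescue")
  expect_equal(decide_retention("weak", unsupported)$decision, "discard")
  # ablation: rescue disabled
  expect_equal(decide_retention("weak", supported,
                                use_monitoring = FALSE)$decision, "discard")
  # contradicted evidence never discards a strong hit; it warns
  rc <- decide_retention("strong", contradicted)
  expect_equal(rc$decision, "retain")
  expect_true(rc$source_warning)
})

test_that("confidence levels follow the evidence ladder", {
  sc <- function(lib, diag, frac = 1) list(n_library_matched = lib,
                                           n_diagnostic_matched = diag,
                                           subformula_plausible_fraction = frac)
  expect_equal(assign_confidence_level(sc(3, 2), library_had_record = TRUE,
                                       library_n_diagnostic = 2), "2a")
  expect_equal(assign_confidence_level(sc(2, 2), library_had_record = FALSE),
               "2b")
  expect_equal(assign_confidence_level(sc(1, 1)), "3")
  expect_equal(assign_confidence_level(sc(0, 0),
                                       formula_unequivocal = TRUE), "4")
  expect_equal(assign_confidence_level(sc(0, 0)), "5")
  # monotone: adding a matched diagnostic never worsens the level
  lev <- confidence_levels()
  for (d in 0:2) {
    a <- assign_confidence_level(sc(d, d))
    b <- assign_confidence_level(sc(d + 1, d + 1))
    expect_lte(match(b, lev), match(a, lev))
  }
})

test_that("standard confirmation needs RT and two fragments", {
  ms2 <- cbind(c(100.9901, 116.9976, 130.0055), c(100, 50, 20))
  expect_equal(confirm_with_standard(5.0, ms2, 5.05, ms2),
               "confirmed_level_1")
  expect_equal(confirm_with_standard(5.0, ms2, 6.0, ms2), "false_positive")
  shifted <- ms2; shifted[, 1] <- shifted[, 1] + 5
  expect_equal(confirm_with_standard(5.0, ms2, 5.0, shifted),
               "false_positive")
})

test_that("cross-polarity dedup merges and keeps the best level", {
  hits <- data.frame(
    suspect_id = c("A", "A", "B"),
    polarity = c("positive", "negative", "positive"),
    confidence_level = c("3", "2b", "5"), stringsAsFactors = FALSE)
  dd <- dedupe_across_polarity(hits)
  expect_equal(nrow(dd), 2)
  a <- dd[dd$suspect_id == "A", ]
  expect_equal(a$confidence_level, "2b")
  expect_equal(a$polarity, "negative;positive")
  expect_equal(dedupe_across_polarity(dd), dd)   # idempotent
  all_unique <- hits[c(1, 3), ]
  expect_equal(nrow(dedupe_across_polarity(all_unique)), 2)
})
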