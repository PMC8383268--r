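# Feature tables, MSP libraries, monitoring metadata, reports.

make_feature_df <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n)),
    site = sample(c("E", "M"), n, replace = TRUE),
    week = "2017-05-01",
    polarity = sample(c("positive", "negative"), n, replace = TRUE),
    mz = runif(n, 80, 600), rt = runif(n, 0.5, 12),
    area = rlnorm(n, 10, 1), stringsAsFactors = FALSE)
  df$trace <- lapply(seq_len(n), function(i)
    cbind(seq(0, 1, length.out = 10), runif(10, 1, 100)))
  df$isotope <- lapply(seq_len(n), function(i) cbind(0:2, c(1, 0.1, 0.05)))
  df$ms2 <- lapply(seq_len(n), function(i)
    if (i %% 3 == 0) matrix(numeric(0), ncol = 2)
    else cbind(runif(3, 50, 300), runif(3, 1, 100)))
  df
}

test_that("feature tables round-trip through CSV", {
  df <- make_feature_df(12, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(df, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back$rejects), 0)
  expect_equal(back$features$feature_id, df$feature_id)
  expect_equal(back$features$mz, df$mz, tolerance = 1e-6)
  for (i in seq_len(nrow(df))) {
    expect_equal(back$features$ms2[[i]], unname(df$ms2[[i]]),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("invalid feature rows land in the reject report with a reason", {
  df <- make_feature_df(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(df, path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  raw$mz[2] <- "-5"   # corrupt row 2: negative m/z
  utils::write.csv(raw, path, row.names = FALSE)
  back <- read_feature_table(path)
  expect_equal(back$rejects$row, 2L)
  expect_match(back$rejects$reason, "m/z")
  expect_equal(nrow(back$features), 3)
  # a missing mandatory column is a schema error
  df2 <- utils::read.csv(path)
  df2$mz <- NULL
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_feature_table(path), "missing column")
})

test_that("MSP library round-trips with diagnostic flags", {
  recs <- list(
    list(name = "tp-one", formula = "C8H6O4", adduct = "[M-H]-",
         precursor_mz = 165.0193, peaks = cbind(c(77.04, 121.0295), c(30, 100)),
         diagnostic = c(FALSE, TRUE), warning = ""),
    list(name = "tp-two", formula = "C4H4ClN3O", adduct = "[M+H]+",
         precursor_mz = 146.0116, peaks = cbind(100.9901, 100),
         diagnostic = TRUE, warning = ""))
  path <- withr::local_tempfile(fileext = ".msp")
  write_spectral_library(recs, path)
  back <- read_spectral_library(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$name, "tp-one")
  expect_equal(back[[1]]$diagnostic, c(FALSE, TRUE))
  expect_equal(back[[2]]$peaks[, 1], 100.9901, tolerance = 1e-6,
               ignore_attr = TRUE)
  # fragment heavier than the precursor flags a warning
  recs[[2]]$peaks <- cbind(200.1, 100)
  write_spectral_library(recs, path)
  flagged <- read_spectral_library(path)
  expect_match(flagged[[2]]$warning, "exceeds precursor")
  # truncated record errors with its index
  writeLines(c("Name: broken", "Num Peaks: 3", "100.1 50"), path)
  expect_error(read_spectral_library(path), "record 1")
})

test_that("monitoring readers validate invariants", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(site = "E", date = "2014-05-15",
                              compound_id = "P001", dose = 120),
                   p, row.names = FALSE)
  apps <- read_application_events(p)
  expect_s3_class(apps$date, "Date")
  utils::write.csv(data.frame(site = "E", date = "2014-05-15",
                              compound_id = "P001", dose = -1),
                   p, row.names = FALSE)
  expect_error(read_application_events(p), "dose")
  utils::write.csv(data.frame(site = "E", week = "2017-05-01",
                              compound_id = "P001", concentration = -0.1),
                   p, row.names = FALSE)
  expect_error(read_detection_records(p), "concentration")
})

test_that("reports are ordered, and CSV/JSON agree", {
  res <- data.frame(
    suspect_id = c("B", "A", "C"), name = c("tp-b", "tp-a", "tp-c"),
    confidence_level = c("3", "1", "2b"), polarity = "positive",
    parent_ids = "P001", site = "E", range_label = "0.1-1",
    last_application_year = 2014L, stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  out <- write_report(res, path)
  expect_equal(out$confidence_level, c("1", "2b", "3"))
  csv <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE,
                         colClasses = c(confidence_level = "character"))
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(names(csv), names(js))
  expect_equal(csv$suspect_id, js$suspect_id)
  # empty result: header-only CSV
  write_report(res[0, ], path)
  expect_equal(nrow(utils::read.csv(paste0(path, ".csv"))), 0)
})
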