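# Readers and writers for all on-disk artifacts: picked-feature tables,
# MSP spectral libraries, monitoring metadata, standards, reports.
#
# Peak lists and chromatogram traces are stored inline in CSV cells as
# "x1:y1;x2:y2;..." pairs so every fixture stays plain text.

.encode_pairs <- function(m) {
  if (is.null(m) || !nrow(m)) return("")
  paste(sprintf("%.6g:%.6g", m[, 1], m[, 2]), collapse = ";")
}

.decode_pairs <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(matrix(numeric(0), ncol = 2))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed x:y pair field")
  matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
}

#' Read a picked LC-HRMS feature table
#'
#' One row per picked peak with site, week, polarity, m/z, retention time,
#' area, and three encoded sub-fields: the chromatogram `trace` ("t:i;..."),
#' the observed `isotope` cluster ("offset:abundance;...") and the `ms2` peak
#' list ("mz:intensity;..."). Rows violating basic invariants (non-positive
#' m/z, negative RT, empty trace) are collected into a reject table with a
#' reason, never silently dropped.
#'
#' @param path CSV path.
#' @return List with `features` (data frame; `trace`, `isotope`, `ms2` are
#'   list-columns of 2-column matrices) and `rejects` (data frame with
#'   `row` and `reason`).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("feature_id", "site", "week", "polarity", "mz", "rt", "area",
            "trace", "isotope", "ms2")
  .check_cols(df, need, "feature table")
  rejects <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- logical(nrow(df))
  trace <- iso <- ms2 <- vector("list", nrow(df))
  mz <- suppressWarnings(as.numeric(df$mz))
  rt <- suppressWarnings(as.numeric(df$rt))
  area <- suppressWarnings(as.numeric(df$area))
  for (i in seq_len(nrow(df))) {
    reason <- NULL
    if (is.na(mz[i]) || mz[i] <= 0) reason <- "non-positive or unparseable m/z"
    else if (is.na(rt[i]) || rt[i] < 0) reason <- "negative or unparseable rt"
    else if (is.na(area[i]) || area[i] < 0) reason <- "invalid area"
    else if (!df$polarity[i] %in% c("positive", "negative"))
      reason <- "unknown polarity"
    else {
      tr <- tryCatch(.decode_pairs(df$trace[i]), error = function(e) NULL)
      if (is.null(tr) || !nrow(tr)) reason <- "empty or malformed trace"
      else {
        trace[[i]] <- tr
        iso[[i]] <- tryCatch(.decode_pairs(df$isotope[i]),
                             error = function(e) matrix(numeric(0), ncol = 2))
        ms2[[i]] <- tryCatch(.decode_pairs(df$ms2[i]),
                             error = function(e) matrix(numeric(0), ncol = 2))
      }
    }
    if (is.null(reason)) keep[i] <- TRUE
    else rejects <- rbind(rejects, data.frame(row = i, reason = reason,
                                              stringsAsFactors = FALSE))
  }
  features <- data.frame(
    feature_id = df$feature_id[keep], site = df$site[keep],
    week = df$week[keep], polarity = df$polarity[keep],
    mz = mz[keep], rt = rt[keep], area = area[keep],
    stringsAsFactors = FALSE
  )
  features$trace <- trace[keep]
  features$isotope <- iso[keep]
  features$ms2 <- ms2[keep]
  list(features = features, rejects = rejects)
}

#' Write a picked feature table
#'
#' @param features Feature data frame as returned by [read_feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  df <- features[c("feature_id", "site", "week", "polarity")]
  df$mz <- sprintf("%.6f", features$mz)
  df$rt <- sprintf("%.4f", features$rt)
  df$area <- sprintf("%.6g", features$area)
  df$trace <- vapply(features$trace, .encode_pairs, character(1))
  df$isotope <- vapply(features$isotope, .encode_pairs, character(1))
  df$ms2 <- vapply(features$ms2, .encode_pairs, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an MSP-format spectral library
#'
#' Minimal NIST-style MSP dialect: records separated by blank lines, header
#' lines `Name:`, `Formula:`, `Adduct:`, `PrecursorMZ:`, `Comments:`,
#' `Num Peaks:`, then one `mz intensity [# diagnostic]` line per fragment.
#' Fragments carrying the `diagnostic` annotation are the structure-specific
#' product ions used as identification evidence. A fragment heavier than the
#' precursor (beyond 10 ppm) flags the record with a load-time warning.
#'
#' @param path MSP file path.
#' @return List of records; each a list with `name`, `formula`, `adduct`,
#'   `precursor_mz`, `peaks` (matrix mz, rel. intensity), `diagnostic`
#'   (logical per peak) and `warning` (character, possibly empty).
#' @export
read_spectral_library <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  recs <- list()
  i <- 1L
  n <- length(lines)
  rec_idx <- 0L
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    rec_idx <- rec_idx + 1L
    hdr <- list()
    while (i <= n && grepl(":", lines[i], fixed = TRUE) &&
           !grepl("^\\s*[0-9.]+[ \t]", lines[i])) {
      kv <- regmatches(lines[i], regexpr(":", lines[i], fixed = TRUE),
                       invert = TRUE)[[1]]
      hdr[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
      i <- i + 1L
    }
    npk <- suppressWarnings(as.integer(hdr[["num peaks"]]))
    if (is.na(npk) || is.null(hdr[["name"]]))
      stop("truncated or malformed MSP record at record ", rec_idx)
    if (i + npk - 1L > n)
      stop("truncated MSP record at record ", rec_idx,
           ": peak list ends early")
    peaks <- matrix(numeric(0), ncol = 2)
    diag <- logical(0)
    for (j in seq_len(npk)) {
      fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(fields) < 2)
        stop("malformed peak line in MSP record ", rec_idx)
      peaks <- rbind(peaks, as.numeric(fields[1:2]))
      diag <- c(diag, any(grepl("diagnostic", fields[-(1:2)], fixed = TRUE)))
      i <- i + 1L
    }
    if (!npk) stop("MSP record ", rec_idx, " has no fragments")
    pre <- suppressWarnings(as.numeric(hdr[["precursormz"]]))
    warn <- character(0)
    if (!is.na(pre) && any(peaks[, 1] > pre * (1 + 10e-6)))
      warn <- "fragment m/z exceeds precursor m/z"
    recs[[rec_idx]] <- list(
      name = hdr[["name"]], formula = hdr[["formula"]],
      adduct = hdr[["adduct"]], precursor_mz = pre,
      peaks = peaks, diagnostic = diag,
      warning = paste(warn, collapse = "; ")
    )
  }
  recs
}

#' Write an MSP-format spectral library
#'
#' @param records List of records in the shape returned by
#'   [read_spectral_library()].
#' @param path Output path.
#' @export
write_spectral_library <- function(records, path) {
  out <- character(0)
  for (r in records) {
    out <- c(out,
      paste0("Name: ", r$name),
      paste0("Formula: ", r$formula),
      paste0("Adduct: ", r$adduct),
      paste0("PrecursorMZ: ", sprintf("%.6f", r$precursor_mz)),
      paste0("Num Peaks: ", nrow(r$peaks)),
      sprintf("%.6f %.6g%s", r$peaks[, 1], r$peaks[, 2],
              ifelse(r$diagnostic, " # diagnostic", "")),
      "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read monitoring metadata
#'
#' `read_application_events` reads pesticide application events (site, date,
#' compound_id, dose in g/ha); `read_detection_records` reads weekly parent
#' concentrations from the regular monitoring program (site, week,
#' compound_id, concentration in ug/L).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_application_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("site", "date", "compound_id", "dose"), "application events")
  if (any(df$dose <= 0)) stop("application dose must be > 0")
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_application_events
#' @export
read_detection_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("site", "week", "compound_id", "concentration"),
              "detection records")
  if (any(df$concentration < 0)) stop("concentration must be >= 0")
  df$week <- as.Date(df$week)
  df
}

#' Write the identification report
#'
#' One row per unique structure, in the style of a newly-(tentatively)-
#' identified-compounds table: TP name, confidence level, concentration range
#' or presence per site, parent compound(s), last application year. Rows are
#' ordered by confidence level then name; the CSV and JSON carry identical
#' fields.
#'
#' @param results Data frame with columns `suspect_id`, `name`,
#'   `confidence_level`, `polarity`, `parent_ids`, `site`, `range_label`,
#'   `last_application_year` (extra columns are carried through).
#' @param path Output path without extension; `<path>.csv` and `<path>.json`
#'   are written.
#' @return Invisibly, the ordered report data frame.
#' @export
write_report <- function(results, path) {
  lev <- confidence_levels()
  if (nrow(results)) {
    ord <- order(match(results$confidence_level, lev), results$name)
    results <- results[ord, , drop = FALSE]
    rownames(results) <- NULL
  }
  utils::write.csv(results, paste0(path, ".csv"), row.names = FALSE, na = "")
  jsonlite::write_json(results, paste0(path, ".json"),
                       dataframe = "rows", na = "null", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
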