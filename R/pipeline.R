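# End-to-end orchestration: suspect-list assembly -> exact-mass matching ->
# peak/RT gates -> fragment evidence -> monitoring integration -> confidence
# levels -> standard confirmation -> cross-polarity dedup -> semiquant ->
# report.

#' Run the full suspect-screening pipeline
#'
#' Executes every stage of the two-step workflow (chemical evidence first,
#' monitoring knowledge second) over a directory of input files, producing a
#' per-structure report and stage-by-stage hit counts. Deterministic: the
#' same inputs always yield the same report.
#'
#' @param config Path to a JSON config file (as written by
#'   [generate_scenario()]) or an equivalent named list. Recognized fields:
#'   the input paths `registry`, `metabolites`, `features`, `library`,
#'   `applications`, `detections`, `rt_calibrants`, `descriptors`,
#'   `internal_standards`, `calibration`, `standards`; options
#'   `use_monitoring` (default TRUE; FALSE ablates the monitoring-rescue
#'   rule), `lookback_years` (default 10), `sample_date` (default: latest
#'   feature week), `out_dir` (default: directory of the config file) and
#'   any [screening_defaults()] name to override a threshold.
#' @return Object of class `pipeline_result`: `counts` (matched,
#'   after_peak_rt, after_fragments, retained, unique, confirmed), `report`
#'   (data frame as written by [write_report()]), `candidates` (per
#'   suspect-polarity evidence table) and `audit_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_dir <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config$out_dir)) config$out_dir <- cfg_dir
  }
  thr <- utils::modifyList(screening_defaults(),
                           config[intersect(names(config),
                                            names(screening_defaults()))])
  use_monitoring <- !isFALSE(config$use_monitoring)
  lookback <- if (is.null(config$lookback_years)) 10 else config$lookback_years
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## load inputs ---------------------------------------------------------
  registry <- utils::read.csv(config$registry, stringsAsFactors = FALSE)
  metabolites <- utils::read.csv(config$metabolites, stringsAsFactors = FALSE)
  ft <- read_feature_table(config$features)
  features <- ft$features
  library_records <- if (!is.null(config$library) && file.exists(config$library))
    read_spectral_library(config$library) else list()
  applications <- read_application_events(config$applications)
  detections <- read_detection_records(config$detections)
  sample_date <- if (!is.null(config$sample_date)) as.Date(config$sample_date)
    else if (nrow(features)) max(as.Date(features$week)) else Sys.Date()

  suspects <- build_suspect_list(registry, metabolites)
  screened <- non_target_subset(suspects)

  descriptors <- if (!is.null(config$descriptors) &&
                     file.exists(config$descriptors))
    utils::read.csv(config$descriptors, stringsAsFactors = FALSE)
    else data.frame(suspect_id = character(0), descriptor = numeric(0))
  rt_model <- NULL
  if (!is.null(config$rt_calibrants) && file.exists(config$rt_calibrants)) {
    cal <- utils::read.csv(config$rt_calibrants, stringsAsFactors = FALSE)
    if (nrow(cal) >= thr$min_calibrants)
      rt_model <- fit_rt_model(cal$descriptor, cal$rt, thr$min_calibrants)
  }

  ## stage 1: exact-mass matching ---------------------------------------
  hits <- match_suspects(features, screened, thr$ms1_tol_ppm)
  n_matched <- nrow(hits)

  ## stage 2: peak shape + RT plausibility ------------------------------
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    f <- hits$feature_row[i]
    pq <- assess_peak_quality(features$trace[[f]], thr$min_points,
                              thr$symmetry_range, thr$min_snr)
    if (!pq$pass) next
    rtp <- "unknown"
    if (!is.null(rt_model)) {
      d <- descriptors$descriptor[match(hits$suspect_id[i],
                                        descriptors$suspect_id)]
      rtp <- rt_plausible(hits$rt[i], if (length(d)) d else NA,
                          rt_model, thr$rt_window)
    }
    keep[i] <- rtp != "fail"
  }
  hits <- hits[keep, , drop = FALSE]
  n_peak_rt <- nrow(hits)

  ## stage 3: fragment evidence -----------------------------------------
  lib_names <- vapply(library_records, `[[`, character(1), "name")
  scores <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- screened[screened$suspect_id == hits$suspect_id[i], ]
    rec <- NULL
    li <- match(s$name, lib_names)
    if (!is.na(li)) rec <- library_records[[li]]
    scores[[i]] <- score_fragments(
      features$ms2[[hits$feature_row[i]]], rec, s$formula, hits$polarity[i],
      thr$ms2_tol_ppm, thr$ms2_tol_mda, thr$ms2_intensity_floor)
  }
  hits$tier <- vapply(scores, `[[`, character(1), "chem_evidence_tier")
  hits$n_lib <- vapply(scores, `[[`, integer(1), "n_library_matched")
  hits$n_diag <- vapply(scores, `[[`, integer(1), "n_diagnostic_matched")
  hits$plaus <- vapply(scores, `[[`, numeric(1),
                       "subformula_plausible_fraction")
  n_fragments <- nrow(hits)   # evidence annotated; nothing discarded yet

  ## collapse to candidates: one per suspect x polarity ------------------
  tier_rank <- c(strong = 1, moderate = 2, weak = 3)
  cand <- list()
  if (nrow(hits)) {
    key <- paste(hits$suspect_id, hits$polarity)
    for (k in unique(key)) {
      grp <- hits[key == k, , drop = FALSE]
      best <- grp[order(tier_rank[grp$tier], -grp$area)[1], , drop = FALSE]
      best$sites <- paste(sort(unique(grp$site)), collapse = ";")
      cand[[k]] <- best
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else hits[0, ]
  rownames(candidates) <- NULL

  ## stage 4: monitoring integration + retention ------------------------
  audit_path <- file.path(out_dir, "audit.jsonl")
  audit_con <- file(audit_path, "w")
  on.exit(close(audit_con), add = TRUE)
  retained <- list()
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, , drop = FALSE]
    s <- screened[screened$suspect_id == cd$suspect_id, ]
    sites <- strsplit(cd$sites, ";")[[1]]
    evs <- lapply(sites, function(st)
      collect_monitoring_evidence(s, st, registry, applications, detections,
                                  sample_date, lookback, metabolites))
    decisions <- lapply(evs, function(e)
      decide_retention(cd$tier, e, use_monitoring))
    retain_i <- which(vapply(decisions, function(d)
      d$decision == "retain", logical(1)))
    decision <- if (length(retain_i)) "retain" else "discard"
    d1 <- if (length(retain_i)) decisions[[retain_i[1]]] else decisions[[1]]
    ev1 <- if (length(retain_i)) evs[[retain_i[1]]] else evs[[1]]
    writeLines(jsonlite::toJSON(list(
      suspect_id = cd$suspect_id, polarity = cd$polarity,
      tier = cd$tier, sites = cd$sites, decision = decision,
      rationale = d1$rationale, source_warning = d1$source_warning),
      auto_unbox = TRUE), audit_con)
    if (decision == "retain") {
      cd$rationale <- d1$rationale
      cd$source_warning <- d1$source_warning
      cd$last_application_year <-
        if (!is.na(ev1$last_application_date))
          as.integer(format(ev1$last_application_date, "%Y")) else NA_integer_
      retained[[length(retained) + 1L]] <- cd
    }
  }
  retained <- if (length(retained)) do.call(rbind, retained) else NULL
  n_retained <- if (is.null(retained)) 0L else nrow(retained)

  ## stage 5: confidence levels + confirmation --------------------------
  standards <- if (!is.null(config$standards) && file.exists(config$standards))
    utils::read.csv(config$standards, stringsAsFactors = FALSE,
                    colClasses = c(ms2 = "character"))
    else data.frame(suspect_id = character(0), rt = numeric(0),
                    ms2 = character(0))
  n_confirmed <- 0L
  if (!is.null(retained)) {
    retained$confidence_level <- NA_character_
    for (i in seq_len(nrow(retained))) {
      s <- screened[screened$suspect_id == retained$suspect_id[i], ]
      li <- match(s$name, lib_names)
      sc <- list(n_library_matched = retained$n_lib[i],
                 n_diagnostic_matched = retained$n_diag[i],
                 subformula_plausible_fraction = retained$plaus[i])
      # formula unequivocal: a single suspect formula fits the mass and the
      # observed isotope cluster agrees with its chlorine count
      f <- retained$feature_row[i]
      expected <- if (retained$polarity[i] == "positive") screened$mz_pos
                  else screened$mz_neg
      n_within <- sum(abs((retained$mz[i] - expected) / expected * 1e6) <=
                        thr$ms1_tol_ppm)
      uneq <- FALSE
      iso <- features$isotope[[f]]
      if (n_within == 1L && !is.null(iso) && nrow(iso) >= 1) {
        obs <- isotope_pattern(iso[, 1], iso[, 2] / iso[1, 2])
        cl_obs <- estimate_chlorine_count(obs)$count
        cl_theo <- .as_counts(s$formula)
        cl_theo <- if ("Cl" %in% names(cl_theo)) cl_theo[["Cl"]] else 0L
        uneq <- cl_obs == cl_theo
      }
      lvl <- assign_confidence_level(
        sc, library_had_record = !is.na(li),
        library_n_diagnostic = if (!is.na(li))
          sum(library_records[[li]]$diagnostic) else 0L,
        formula_unequivocal = uneq)
      si <- match(retained$suspect_id[i], standards$suspect_id)
      if (!is.na(si)) {
        res <- confirm_with_standard(
          retained$rt[i], features$ms2[[f]],
          standards$rt[si], .decode_pairs(standards$ms2[si]),
          thr$rt_tol_confirm, thr$ms2_tol_ppm, thr$ms2_tol_mda)
        if (res == "confirmed_level_1") lvl <- "1"
      }
      retained$confidence_level[i] <- lvl
    }
    n_confirmed <- sum(retained$confidence_level == "1")
  }

  ## stage 6: cross-polarity dedup --------------------------------------
  unique_structures <- if (is.null(retained)) NULL
    else dedupe_across_polarity(retained)
  n_unique <- if (is.null(unique_structures)) 0L else nrow(unique_structures)

  ## stage 7: semiquantification ----------------------------------------
  calibration <- if (!is.null(config$calibration) &&
                     file.exists(config$calibration))
    utils::read.csv(config$calibration, stringsAsFactors = FALSE) else NULL
  is_tab <- if (!is.null(config$internal_standards) &&
                file.exists(config$internal_standards))
    utils::read.csv(config$internal_standards, stringsAsFactors = FALSE)
    else NULL
  report <- data.frame()
  if (!is.null(unique_structures) && nrow(unique_structures)) {
    rows <- list()
    for (i in seq_len(nrow(unique_structures))) {
      u <- unique_structures[i, , drop = FALSE]
      s <- screened[screened$suspect_id == u$suspect_id, ]
      sites <- strsplit(u$sites, ";")[[1]]
      labels <- vapply(sites, function(st) {
        if (is.null(calibration)) return("detected")
        cc <- calibration[calibration$compound_id == u$suspect_id &
                            calibration$site == st, , drop = FALSE]
        if (!nrow(cc)) return("detected")
        curve <- fit_matrix_calibration(cc$level, cc$area, cc$is_area,
                                        cc$blank_area[1], cc$blank_is_area[1])
        # sample response: largest matching feature area, IS-normalized
        fh <- hits[hits$suspect_id == u$suspect_id & hits$site == st, ,
                   drop = FALSE]
        if (!nrow(fh)) return("detected")
        j <- which.max(fh$area)
        isa <- if (!is.null(is_tab)) {
          m <- is_tab[is_tab$site == st & is_tab$week == fh$week[j] &
                        is_tab$polarity == fh$polarity[j], , drop = FALSE]
          if (nrow(m)) m$is_area[1] else 1
        } else 1
        as.character(semiquantify(fh$area[j] / isa, curve))
      }, character(1))
      rows[[i]] <- data.frame(
        suspect_id = u$suspect_id, name = s$name,
        confidence_level = u$confidence_level, polarity = u$polarity,
        parent_ids = s$parent_ids, site = paste(sites, collapse = ";"),
        range_label = paste(labels, collapse = ";"),
        last_application_year = u$last_application_year,
        source_warning = isTRUE(u$source_warning),
        stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, rows)
  }
  report <- write_report(report, file.path(out_dir, "report"))

  structure(list(
    counts = list(matched = n_matched, after_peak_rt = n_peak_rt,
                  after_fragments = n_fragments, retained = n_retained,
                  unique = n_unique, confirmed = n_confirmed),
    report = report, candidates = candidates, audit_path = audit_path),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  c0 <- x$counts
  cat("Suspect-screening pipeline result\n")
  cat(sprintf("  %5d suspect hits (exact mass)\n", c0$matched))
  cat(sprintf("  %5d after peak-shape / RT gates\n", c0$after_peak_rt))
  cat(sprintf("  %5d with fragment evidence scored\n", c0$after_fragments))
  cat(sprintf("  %5d candidates retained (chemistry + monitoring)\n",
              c0$retained))
  cat(sprintf("  %5d unique structures after polarity dedup\n", c0$unique))
  cat(sprintf("  %5d confirmed by reference standard\n", c0$confirmed))
  invisible(x)
}
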