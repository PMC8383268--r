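# Monitoring-knowledge half of the workflow: evidence collection from
# application/detection metadata, the retention decision, confidence-level
# assignment, standard confirmation, and cross-polarity deduplication.

#' Ordered identification confidence levels
#'
#' Schymanski-style ordinal scale: 1 (confirmed by reference standard),
#' 2a (library spectrum match), 2b (diagnostic-fragment evidence),
#' 3 (tentative, one supporting fragment), 4 (unequivocal molecular formula),
#' 5 (exact mass only). Lower means more confident.
#'
#' @return Character vector of the six levels in confidence order.
#' @export
confidence_levels <- function() c("1", "2a", "2b", "3", "4", "5")

#' Collect monitoring evidence for a suspect at a site
#'
#' Summarizes what the national monitoring program knows about the suspect's
#' parent compound(s) at the sampling site: registration, application history
#' within a lookback window, detections of the parent, and a mobility
#' comparison (TP K_foc below the parent's implies higher aqueous mobility).
#' Source plausibility is `supported` when any site-level flag is true,
#' `contradicted` when no parent is registered, applied or detected anywhere,
#' and `neutral` otherwise.
#'
#' @param suspect One row of the suspect list (added parents count as their
#'   own parent).
#' @param site Site id.
#' @param registry Registry data frame (for `registered_sites`).
#' @param applications Application events ([read_application_events()]).
#' @param detections Detection records ([read_detection_records()]).
#' @param at_date Reference date closing the lookback window (sample date).
#' @param lookback_years Length of the application lookback window in years.
#' @param metabolites Optional key-metabolite table supplying `parent_k_foc`.
#' @return List of class `monitoring_evidence` with fields
#'   `parent_registered_at_site`, `parent_applied_at_site`,
#'   `last_application_date`, `parent_detected_at_site`,
#'   `parent_detection_weeks`, `mobility_flag`, `source_plausibility`.
#' @export
collect_monitoring_evidence <- function(suspect, site, registry,
                                        applications, detections,
                                        at_date = Sys.Date(),
                                        lookback_years = 10,
                                        metabolites = NULL) {
  parents <- unlist(strsplit(suspect$parent_ids, ";", fixed = TRUE))
  if (!length(parents) || !nzchar(parents[1])) parents <- suspect$suspect_id
  at_date <- as.Date(at_date)
  window_start <- at_date - round(lookback_years * 365.25)

  reg <- registry[registry$compound_id %in% parents, , drop = FALSE]
  reg_sites <- unlist(strsplit(
    if ("registered_sites" %in% names(reg)) reg$registered_sites else character(0),
    ";", fixed = TRUE))
  registered_here <- site %in% reg_sites
  registered_anywhere <- length(reg_sites) > 0

  app <- applications[applications$compound_id %in% parents, , drop = FALSE]
  app_window <- app[as.Date(app$date) >= window_start &
                      as.Date(app$date) <= at_date, , drop = FALSE]
  applied_here <- any(app_window$site == site)
  last_app <- if (nrow(app_window[app_window$site == site, , drop = FALSE]))
    max(as.Date(app_window$date[app_window$site == site])) else as.Date(NA)

  det <- detections[detections$compound_id %in% parents &
                      detections$concentration > 0, , drop = FALSE]
  det_window <- det[as.Date(det$week) >= window_start &
                      as.Date(det$week) <= at_date, , drop = FALSE]
  detected_here <- any(det_window$site == site)
  det_weeks <- sort(unique(as.Date(det_window$week[det_window$site == site])))

  mobility <- NA
  k_tp <- suspect$k_foc
  k_parent <- NA_real_
  if (!is.null(metabolites) && nrow(metabolites)) {
    m <- metabolites[metabolites$tp_id == suspect$suspect_id, , drop = FALSE]
    if (nrow(m) && "parent_k_foc" %in% names(m))
      k_parent <- suppressWarnings(min(m$parent_k_foc, na.rm = TRUE))
    if (!is.finite(k_parent)) k_parent <- NA_real_
  }
  if (!is.na(k_tp) && !is.na(k_parent)) mobility <- k_tp < k_parent

  plausibility <- if (registered_here || applied_here || detected_here)
    "supported"
  else if (!registered_anywhere && !nrow(app_window) && !nrow(det_window))
    "contradicted"
  else "neutral"

  structure(list(
    parent_registered_at_site = registered_here,
    parent_applied_at_site = applied_here,
    last_application_date = last_app,
    parent_detected_at_site = detected_here,
    parent_detection_weeks = det_weeks,
    mobility_flag = mobility,
    source_plausibility = plausibility
  ), class = "monitoring_evidence")
}

#' Retention decision integrating chemical and monitoring evidence
#'
#' Hits with strong or moderate chemical evidence are always retained.
#' Weak-evidence hits — the ones a chemistry-only workflow would discard —
#' are rescued when monitoring data show the presence (detection) or use
#' (application) of a parent compound at the sampling site. Contradicted
#' source plausibility never discards a strong hit; it attaches a source
#' warning instead (a confidently identified structure may simply originate
#' from a source other than the suspected parent).
#'
#' @param tier Chemical-evidence tier: `"strong"`, `"moderate"` or `"weak"`.
#' @param evidence A `monitoring_evidence` object.
#' @param use_monitoring Set FALSE to ablate the monitoring-rescue rule
#'   (chemistry-only workflow).
#' @return List: `decision` (`"retain"` / `"discard"`), `rationale` (code),
#'   `source_warning` (logical).
#' @export
decide_retention <- function(tier, evidence, use_monitoring = TRUE) {
  warn <- identical(evidence$source_plausibility, "contradicted") &&
    tier == "strong"
  if (tier %in% c("strong", "moderate"))
    return(list(decision = "retain",
                rationale = paste0("chemical_evidence_", tier),
                source_warning = warn))
  rescued <- use_monitoring &&
    (isTRUE(evidence$parent_applied_at_site) ||
       isTRUE(evidence$parent_detected_at_site))
  if (rescued)
    return(list(decision = "retain", rationale = "monitoring_rescue",
                source_warning = FALSE))
  list(decision = "discard", rationale = "weak_no_monitoring_support",
       source_warning = FALSE)
}

#' Assign an identification confidence level
#'
#' Maps the accumulated fragment and formula evidence to the ordinal scale of
#' [confidence_levels()]: 2a for a full library-spectrum match (>= 2 library
#' fragments recovered including every diagnostic one), 2b for >= 2
#' diagnostic fragments without the full match, 3 for exactly one supporting
#' fragment, 4 for no usable fragments but an unequivocal molecular formula
#' (e.g. the chlorine isotope pattern fixes the Cl count and a single suspect
#' formula fits the exact mass), 5 otherwise. Level 1 is reserved for
#' [confirm_with_standard()].
#'
#' @param scores Fragment scores from [score_fragments()].
#' @param library_had_record Was a library spectrum available for the suspect?
#' @param library_n_diagnostic Number of diagnostic fragments in that record.
#' @param formula_unequivocal Is the molecular formula unequivocal?
#' @return One of `"2a"`, `"2b"`, `"3"`, `"4"`, `"5"`.
#' @export
assign_confidence_level <- function(scores, library_had_record = FALSE,
                                    library_n_diagnostic = 0L,
                                    formula_unequivocal = FALSE) {
  n_lib <- scores$n_library_matched
  n_diag <- scores$n_diagnostic_matched
  if (library_had_record && n_lib >= 2L && n_diag >= library_n_diagnostic)
    return("2a")
  if (n_diag >= 2L) return("2b")
  if (n_lib == 1L || n_diag == 1L) return("3")
  if (formula_unequivocal) return("4")
  "5"
}

#' Confirm a candidate against a purchased reference standard
#'
#' Confirmation (level 1) requires retention-time agreement within the
#' tolerance and recovery of at least two of the standard's fragments in the
#' candidate's MS2 spectrum; anything else refutes the identity and the hit
#' is a false positive.
#'
#' @param hit_rt,hit_ms2 Candidate RT (minutes) and MS2 peak matrix.
#' @param standard_rt,standard_ms2 Reference-standard RT and MS2 peak matrix.
#' @param rt_tol RT tolerance in minutes.
#' @param tol_ppm,tol_mda MS2 match tolerance.
#' @return `"confirmed_level_1"` or `"false_positive"`.
#' @export
confirm_with_standard <- function(hit_rt, hit_ms2, standard_rt, standard_ms2,
                                  rt_tol = screening_defaults()$rt_tol_confirm,
                                  tol_ppm = screening_defaults()$ms2_tol_ppm,
                                  tol_mda = screening_defaults()$ms2_tol_mda) {
  if (abs(hit_rt - standard_rt) > rt_tol) return("false_positive")
  if (is.null(hit_ms2) || !nrow(hit_ms2) ||
      is.null(standard_ms2) || !nrow(standard_ms2))
    return("false_positive")
  n_match <- sum(vapply(standard_ms2[, 1], function(mz) {
    any(abs(hit_ms2[, 1] - mz) <= .ms2_tol_da(mz, tol_ppm, tol_mda))
  }, logical(1)))
  if (n_match >= 2L) "confirmed_level_1" else "false_positive"
}

#' Collapse retained hits detected in both polarities
#'
#' One record per suspect structure: polarities are merged and the best
#' (lowest, most confident) level is kept. Idempotent.
#'
#' @param hits Data frame with at least `suspect_id`, `polarity` and
#'   `confidence_level`.
#' @return Data frame with one row per suspect; `polarity` becomes a
#'   ";"-joined sorted list of the polarities observed.
#' @export
dedupe_across_polarity <- function(hits) {
  if (!nrow(hits)) return(hits)
  lev <- confidence_levels()
  out <- list()
  for (id in unique(hits$suspect_id)) {
    grp <- hits[hits$suspect_id == id, , drop = FALSE]
    best <- grp[order(match(grp$confidence_level, lev))[1], , drop = FALSE]
    pols <- sort(unique(unlist(strsplit(grp$polarity, ";", fixed = TRUE))))
    best$polarity <- paste(pols, collapse = ";")
    out[[id]] <- best
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
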