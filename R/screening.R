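# Chemical-evidence half of the two-step workflow: exact-mass suspect
# matching, peak-shape gating, retention-time plausibility, and fragment
# evidence scoring.

#' Default screening thresholds
#'
#' All gate thresholds in one place; every entry can be overridden via the
#' pipeline config. MS1/MS2 tolerances, peak-shape criteria and the RT window
#' are conventional suspect-screening settings.
#'
#' @return Named list of thresholds.
#' @export
screening_defaults <- function() {
  list(
    ms1_tol_ppm = 5,          # suspect matching window
    ms2_tol_ppm = 10,         # fragment matching, ppm part
    ms2_tol_mda = 5,          # fragment matching, absolute floor (mDa)
    min_points = 7,           # points across the chromatographic peak
    symmetry_range = c(0.5, 2.0),
    min_snr = 3,
    rt_window = 3,            # multiples of RT-model residual spread
    min_calibrants = 5,
    ms2_intensity_floor = 0.02,  # fraction of base peak entering plausibility
    rt_tol_confirm = 0.2      # minutes, standard confirmation
  )
}

#' Match features against the suspect list by exact mass
#'
#' Pairs every feature with every suspect whose expected m/z in the feature's
#' polarity lies within `tol_ppm`. One feature may hit several suspects and
#' one suspect several features; downstream gates thin the list.
#'
#' @param features Feature data frame ([read_feature_table()]).
#' @param suspects Suspect list ([build_suspect_list()]).
#' @param tol_ppm MS1 mass tolerance in ppm.
#' @return Data frame of candidate hits: `suspect_id`, `feature_id`, `site`,
#'   `week`, `polarity`, `mz`, `rt`, `area`, `mass_error_ppm`, plus the
#'   feature row index `feature_row`.
#' @export
match_suspects <- function(features, suspects,
                           tol_ppm = screening_defaults()$ms1_tol_ppm) {
  empty <- data.frame(
    suspect_id = character(0), feature_id = character(0), site = character(0),
    week = character(0), polarity = character(0), mz = numeric(0),
    rt = numeric(0), area = numeric(0), mass_error_ppm = numeric(0),
    feature_row = integer(0), stringsAsFactors = FALSE)
  if (!nrow(features) || !nrow(suspects)) return(empty)
  out <- list()
  for (i in seq_len(nrow(features))) {
    expected <- if (features$polarity[i] == "positive") suspects$mz_pos
                else suspects$mz_neg
    err <- (features$mz[i] - expected) / expected * 1e6
    j <- which(abs(err) <= tol_ppm)
    if (!length(j)) next
    out[[length(out) + 1L]] <- data.frame(
      suspect_id = suspects$suspect_id[j], feature_id = features$feature_id[i],
      site = features$site[i], week = features$week[i],
      polarity = features$polarity[i], mz = features$mz[i],
      rt = features$rt[i], area = features$area[i],
      mass_error_ppm = err[j], feature_row = i, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assess chromatographic peak quality
#'
#' A peak passes when it has enough points across it, acceptable symmetry and
#' sufficient signal-to-noise. Points across the peak are counted above 10%
#' of the baseline-corrected apex; symmetry is the right/left half-width
#' ratio at half maximum; noise is the standard deviation of the lower
#' quartile of intensities (the trace tails).
#'
#' @param trace Two-column matrix (time, intensity).
#' @param min_points Minimum points across the peak.
#' @param symmetry_range Acceptable (right/left) half-width ratio interval.
#' @param min_snr Minimum apex / baseline-noise ratio.
#' @return List with `pass` (logical) and `score` in \[0, 1\] (geometric mean
#'   of the three per-criterion sub-scores, capped at 1).
#' @export
assess_peak_quality <- function(trace,
                                min_points = screening_defaults()$min_points,
                                symmetry_range = screening_defaults()$symmetry_range,
                                min_snr = screening_defaults()$min_snr) {
  if (is.null(trace) || !nrow(trace)) return(list(pass = FALSE, score = 0))
  y <- trace[, 2]
  baseline <- stats::median(sort(y)[seq_len(max(1L, floor(length(y) / 4)))])
  apex <- max(y) - baseline
  if (apex <= 0) return(list(pass = FALSE, score = 0))
  above <- y - baseline > 0.1 * apex
  n_pts <- sum(above)
  # half-widths about the apex at half maximum
  i_apex <- which.max(y)
  half <- baseline + apex / 2
  left <- which(y[seq_len(i_apex)] < half)
  right <- which(y[i_apex:length(y)] < half)
  lw <- if (length(left)) i_apex - max(left) else i_apex
  rw <- if (length(right)) min(right) - 1L else length(y) - i_apex + 1L
  asym <- rw / max(lw, 1L)
  # noise = residual about a 3-point running mean; apex from the smooth part
  n <- length(y)
  smooth <- if (n >= 3)
    c(y[1], (y[-c(1, 2)] + y[-c(1, n)] + y[-c(n - 1, n)]) / 3, y[n])
  else y
  noise <- stats::sd(y - smooth)
  snr <- if (is.na(noise) || noise == 0) Inf
         else (max(smooth) - baseline) / noise
  s_pts <- min(1, n_pts / min_points)
  s_sym <- if (asym >= symmetry_range[1] && asym <= symmetry_range[2]) 1
           else max(0, 1 - abs(log2(asym)))
  s_snr <- min(1, snr / (2 * min_snr))
  pass <- n_pts >= min_points &&
    asym >= symmetry_range[1] && asym <= symmetry_range[2] &&
    snr >= min_snr
  list(pass = pass, score = (s_pts * s_sym * s_snr)^(1 / 3))
}

#' Fit a retention-time plausibility model
#'
#' Ordinary least-squares line relating a hydrophobicity descriptor (e.g. a
#' log partition-coefficient estimate, supplied as data, never computed
#' internally) to retention time, from compounds with known RT.
#'
#' @param descriptor Numeric descriptor values of the calibrants.
#' @param rt Observed retention times (minutes).
#' @param min_calibrants Minimum number of calibrants.
#' @return Object of class `rt_model`: slope, intercept, residual spread
#'   (SD of residuals) and `n_calibrants`.
#' @export
fit_rt_model <- function(descriptor, rt,
                         min_calibrants = screening_defaults()$min_calibrants) {
  ok <- is.finite(descriptor) & is.finite(rt)
  if (sum(ok) < min_calibrants)
    stop("need at least ", min_calibrants, " calibrants, got ", sum(ok))
  fit <- stats::lm(rt[ok] ~ descriptor[ok])
  spread <- stats::sd(stats::residuals(fit))
  if (!is.finite(spread) || spread == 0) spread <- 1e-6
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_spread = spread,
                 n_calibrants = sum(ok)),
            class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("RT plausibility model: rt =", format(x$intercept, digits = 4), "+",
      format(x$slope, digits = 4), "* descriptor\n")
  cat("  residual spread:", format(x$residual_spread, digits = 3),
      "min;", x$n_calibrants, "calibrants\n")
  invisible(x)
}

#' Retention-time plausibility of a hit
#'
#' @param rt_observed Observed retention time (minutes).
#' @param descriptor Suspect's hydrophobicity descriptor (NA when unknown).
#' @param model An `rt_model`.
#' @param window Acceptance window as a multiple of the model's residual
#'   spread.
#' @return `"pass"`, `"fail"`, or `"unknown"` when the descriptor is missing
#'   (missing data is never treated as a failure).
#' @export
rt_plausible <- function(rt_observed, descriptor, model,
                         window = screening_defaults()$rt_window) {
  if (is.na(descriptor)) return("unknown")
  pred <- model$intercept + model$slope * descriptor
  if (abs(rt_observed - pred) <= window * model$residual_spread) "pass"
  else "fail"
}

# Fragment m/z matching tolerance: the larger of ppm- and mDa-based windows.
.ms2_tol_da <- function(mz, tol_ppm, tol_mda) {
  pmax(mz * tol_ppm * 1e-6, tol_mda * 1e-3)
}

#' Score MS2 fragment evidence for a candidate hit
#'
#' Counts library fragments recovered in the observed MS2 spectrum (and the
#' diagnostic subset), and computes the fraction of observed fragments (above
#' an intensity floor) explainable as subformulas of the precursor ion. The
#' hit's chemical-evidence tier summarizes this: `strong` for >= 2 diagnostic
#' matches, or >= 2 library matches with >= 0.8 of fragments plausible;
#' `moderate` for exactly one diagnostic/library match with >= 0.5 plausible;
#' `weak` otherwise (including an empty spectrum).
#'
#' @param ms2 Two-column matrix (mz, intensity); may have zero rows.
#' @param library_record Matching spectral-library record or NULL.
#' @param precursor_formula Neutral formula of the suspect (string).
#' @param polarity `"positive"` or `"negative"`.
#' @param tol_ppm,tol_mda MS2 match tolerance (larger of the two applies).
#' @param intensity_floor Fraction of the base peak below which observed
#'   fragments are ignored in the plausibility denominator.
#' @return List: `n_library_matched`, `n_diagnostic_matched`,
#'   `subformula_plausible_fraction`, `chem_evidence_tier`.
#' @export
score_fragments <- function(ms2, library_record, precursor_formula, polarity,
                            tol_ppm = screening_defaults()$ms2_tol_ppm,
                            tol_mda = screening_defaults()$ms2_tol_mda,
                            intensity_floor = screening_defaults()$ms2_intensity_floor) {
  n_lib <- 0L
  n_diag <- 0L
  frac <- 0
  has_ms2 <- !is.null(ms2) && nrow(ms2) > 0
  if (has_ms2 && !is.null(library_record)) {
    for (k in seq_len(nrow(library_record$peaks))) {
      lmz <- library_record$peaks[k, 1]
      tol <- .ms2_tol_da(lmz, tol_ppm, tol_mda)
      if (any(abs(ms2[, 1] - lmz) <= tol)) {
        n_lib <- n_lib + 1L
        if (library_record$diagnostic[k]) n_diag <- n_diag + 1L
      }
    }
  }
  if (has_ms2) {
    charge <- if (polarity == "positive") 1L else -1L
    adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
    prec <- .as_counts(precursor_formula)
    prec["H"] <- (if ("H" %in% names(prec)) prec[["H"]] else 0L) + charge
    if (prec[["H"]] < 0L) prec <- prec[names(prec) != "H"]
    keep <- ms2[, 2] >= intensity_floor * max(ms2[, 2])
    obs <- ms2[keep, 1]
    if (length(obs)) {
      plaus <- vapply(obs, function(mz) {
        nrow(enumerate_subformulas(prec, mz, charge = charge,
                                   tol_ppm = max(tol_ppm, 10))) > 0
      }, logical(1))
      frac <- mean(plaus)
    }
  }
  tier <- "weak"
  if (n_diag >= 2L || (n_lib >= 2L && frac >= 0.8)) tier <- "strong"
  else if ((n_diag == 1L || n_lib == 1L) && frac >= 0.5) tier <- "moderate"
  list(n_library_matched = n_lib, n_diagnostic_matched = n_diag,
       subformula_plausible_fraction = frac, chem_evidence_tier = tier)
}
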