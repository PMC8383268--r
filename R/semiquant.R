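# Matrix-matched, internal-standard-normalized semiquantification into
# ordinal concentration ranges.

.RANGE_LABELS <- c("<0.1", "0.1-1", "1-10", ">10", "<1", "detected")

#' Concentration-range labels
#'
#' The four ordinal ranges used for semiquantification, plus the two fallback
#' labels: `"<1"` when the lowest calibration point was not detected, and
#' `"detected"` when the matrix-matched curve shows no linearity.
#'
#' @return Character vector of the six labels.
#' @export
concentration_ranges <- function() .RANGE_LABELS

#' Fit a matrix-matched calibration curve
#'
#' Least-squares line through blank-subtracted, internal-standard-normalized
#' responses at the matrix-matched levels 0.1, 1 and 10 ug/L. The curve is
#' flagged non-linear when fewer than two points are detected, the fit's
#' coefficient of determination falls below `r2_threshold`, or the slope is
#' not positive. `lowest_point_detected` records whether the 0.1 ug/L level
#' rose above blank + noise.
#'
#' @param level Nominal concentrations (ug/L), normally c(0.1, 1, 10).
#' @param area Analyte peak areas at each level.
#' @param is_area Internal-standard areas at each level.
#' @param blank_area Analyte area in the matrix blank (scalar or per level).
#' @param blank_is_area Internal-standard area in the blank.
#' @param noise_floor Minimum blank-subtracted normalized response for a
#'   level to count as detected, as a fraction of the top-level response.
#' @param r2_threshold Linearity criterion on R-squared.
#' @return Object of class `calibration_curve`: `points` (level, response,
#'   detected), `slope`, `intercept`, `linearity_ok`, `lowest_point_detected`.
#' @export
fit_matrix_calibration <- function(level, area, is_area,
                                   blank_area = 0, blank_is_area = 1,
                                   noise_floor = 0.002, r2_threshold = 0.98) {
  stopifnot(length(level) == length(area), length(area) == length(is_area))
  resp <- area / is_area - blank_area / blank_is_area
  detected <- resp > noise_floor * max(resp, 0)
  lowest_detected <- if (any(level == min(level))) {
    any(detected[level == min(level)])
  } else FALSE
  pts <- data.frame(level = level, response = resp, detected = detected)
  slope <- intercept <- NA_real_
  lin <- FALSE
  use <- detected
  if (sum(use) >= 2) {
    fit <- stats::lm(resp[use] ~ level[use])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    ss_tot <- sum((resp[use] - mean(resp[use]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
    lin <- is.finite(r2) && r2 >= r2_threshold && is.finite(slope) && slope > 0
  }
  structure(list(points = pts, slope = slope, intercept = intercept,
                 linearity_ok = lin, lowest_point_detected = lowest_detected),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Matrix-matched calibration:",
      if (x$linearity_ok) "linear" else "no linearity", "\n")
  if (x$linearity_ok)
    cat("  response =", format(x$intercept, digits = 4), "+",
        format(x$slope, digits = 4), "* c\n")
  cat("  lowest point detected:", x$lowest_point_detected, "\n")
  invisible(x)
}

#' Semiquantify a detection into a concentration range
#'
#' Estimates the concentration from the sample's IS-normalized area via the
#' calibration line, then bins it into the ordinal ranges with left-closed
#' boundaries at 0.1, 1 and 10 ug/L. Fallbacks: a non-linear curve yields
#' `"detected"`; when the lowest calibration point was not detected, any
#' estimate below 1 ug/L is reported as `"<1"`. A negative estimate maps to
#' `"<0.1"` with an audit warning attribute.
#'
#' @param sample_response IS-normalized (and blank-subtracted) sample area.
#' @param curve A `calibration_curve`.
#' @return One of the [concentration_ranges()] labels; attribute `estimate`
#'   carries the point estimate (ug/L) when the curve is linear, and
#'   attribute `warning` flags a negative estimate.
#' @export
semiquantify <- function(sample_response, curve) {
  if (!curve$linearity_ok) return(structure("detected", estimate = NA_real_))
  c_est <- (sample_response - curve$intercept) / curve$slope
  warn <- NULL
  if (c_est < 0) {
    label <- "<0.1"
    warn <- "negative concentration estimate truncated to <0.1"
  } else if (!curve$lowest_point_detected && c_est < 1) {
    label <- "<1"
  } else if (c_est < 0.1) {
    label <- "<0.1"
  } else if (c_est < 1) {
    label <- "0.1-1"
  } else if (c_est < 10) {
    label <- "1-10"
  } else {
    label <- ">10"
  }
  structure(label, estimate = c_est, warning = warn)
}
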