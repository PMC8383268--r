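# Elemental-formula arithmetic, monoisotopic masses, adduct/ion m/z,
# isotope-pattern simulation, chlorine counting, subformula enumeration.

# IUPAC 2021 monoisotopic (lightest-isotope) atomic masses, Da.
.ELEMENT_MASS <- c(
  C  = 12.000000000,
  H  = 1.007825032,
  N  = 14.003074004,
  O  = 15.994914620,
  S  = 31.972071174,
  P  = 30.973761998,
  F  = 18.998403163,
  Cl = 34.968852682,
  Br = 78.918337600
)

.PROTON_MASS   <- 1.00727646
.ELECTRON_MASS <- 0.00054858

# Natural isotopologue distributions at unit-mass-offset resolution:
# per element, probability of +0/+1/+2 Da relative to the lightest isotope.
.ELEMENT_ISO <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425),
  P  = 1,
  F  = 1,
  Cl = c(0.7576, 0, 0.2424),
  Br = c(0.5069, 0, 0.4931)
)

.SUPPORTED_ELEMENTS <- names(.ELEMENT_MASS)

#' Parse an elemental formula in Hill-like notation
#'
#' Converts a formula string such as \code{"C4H4ClN3O"} into a named integer
#' vector of element counts. Supported elements: C, H, N, O, S, P, F, Cl, Br.
#'
#' @param text Formula string, e.g. \code{"C8H6O4"}.
#' @return Named integer vector of counts over the supported elements
#'   (zero counts dropped), in Hill order.
#' @examples
#' parse_formula("C4H4ClN3O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula string must be a single non-empty string")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("cannot parse formula: ", sQuote(text))
  counts <- integer(0)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    if (!sym %in% .SUPPORTED_ELEMENTS)
      stop("unknown element ", sQuote(sym), " in formula ", sQuote(text))
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("formula has no atoms: ", sQuote(text))
  .hill_order(counts)
}

# Hill order: C first, H second, rest alphabetical (C absent: all alphabetical).
.hill_order <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts[ord]
}

#' Format element counts as a Hill-notation string
#'
#' Inverse of [parse_formula()]: \code{parse_formula(format_formula(f))}
#' reproduces \code{f}.
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(counts) {
  counts <- .as_counts(counts)
  counts <- .hill_order(counts[counts > 0L])
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

# Accept either a formula string or a named count vector.
.as_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) && length(f) > 0)
    stop("element counts must be named")
  bad <- setdiff(names(f), .SUPPORTED_ELEMENTS)
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(f < 0)) stop("negative element count")
  storage.mode(f) <- "integer"
  f
}

#' Monoisotopic mass of a neutral elemental composition
#'
#' @param f Formula string or named count vector.
#' @return Mass in Da (sum of lightest-isotope atomic masses).
#' @examples
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  counts <- .as_counts(f)
  if (!length(counts)) return(0)
  sum(counts * .ELEMENT_MASS[names(counts)])
}

#' Supported electrospray adducts
#'
#' The screening workflow supports singly charged protonated and deprotonated
#' species only, mirroring routine positive/negative-mode acquisition.
#'
#' @return Data frame with columns \code{label}, \code{polarity},
#'   \code{proton_delta} and \code{charge}.
#' @export
adduct_table <- function() {
  data.frame(
    label        = c("[M+H]+", "[M-H]-"),
    polarity     = c("positive", "negative"),
    proton_delta = c(1L, -1L),
    charge       = c(1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of an ion
#'
#' Two modes. With `adduct`, `f` is a neutral molecule and the m/z is the
#' protonated/deprotonated species: mass(M) + delta * 1.00727646. With
#' `charge`, `f` is the ionic elemental composition itself and the m/z is its
#' monoisotopic mass corrected for electron gain/loss
#' (mass - charge * 0.00054858). Only |charge| = 1 is supported. Values are
#' never rounded internally; round only for presentation.
#'
#' @param f Formula string or named count vector.
#' @param adduct `"[M+H]+"` or `"[M-H]-"` (neutral-molecule mode).
#' @param charge +1 or -1 (ionic-composition mode). Give exactly one of
#'   `adduct` / `charge`.
#' @return m/z in Th.
#' @examples
#' ion_mz("C4H4ClN3O", adduct = "[M+H]+")   # desphenyl-chloridazon, PI
#' ion_mz("C7H5O2", charge = -1)            # benzoate-type fragment anion
#' @export
ion_mz <- function(f, adduct = NULL, charge = NULL) {
  if (is.null(adduct) == is.null(charge))
    stop("give exactly one of `adduct` or `charge`")
  m <- monoisotopic_mass(f)
  if (!is.null(adduct)) {
    tab <- adduct_table()
    i <- match(adduct, tab$label)
    if (is.na(i)) stop("unsupported adduct ", sQuote(adduct))
    return(m + tab$proton_delta[i] * .PROTON_MASS)
  }
  if (!charge %in% c(1L, -1L, 1, -1)) stop("only singly charged ions supported")
  m - charge * .ELECTRON_MASS
}

#' Simulate a coarse isotope pattern
#'
#' Convolves natural isotopologue distributions over all atoms at
#' unit-mass-offset resolution. The A+2 signature of chlorine
#' (Cl-37/Cl-35 ~ 0.32 per chlorine) dominates when Cl is present.
#'
#' @param f Formula string or named count vector.
#' @param n_peaks Number of peaks to return (offsets 0 .. n_peaks-1), >= 2.
#' @return Object of class `isotope_pattern`: data frame with `offset` (Da,
#'   nominal) and `abundance` (monoisotopic peak = 1).
#' @examples
#' simulate_isotope_pattern("C3H2ClN2")  # A+2/A close to 0.32
#' @export
simulate_isotope_pattern <- function(f, n_peaks = 4L) {
  counts <- .as_counts(f)
  if (n_peaks < 2L) stop("n_peaks must be >= 2")
  dist <- 1
  for (el in names(counts)) {
    d <- .ELEMENT_ISO[[el]]
    for (i in seq_len(counts[[el]])) {
      dist <- .convolve_trunc(dist, d, n_peaks)
    }
  }
  dist <- c(dist, numeric(max(0L, n_peaks - length(dist))))[seq_len(n_peaks)]
  isotope_pattern(offset = seq_len(n_peaks) - 1, abundance = dist / dist[1])
}

.convolve_trunc <- function(a, b, n_max) {
  out <- numeric(min(length(a) + length(b) - 1L, n_max))
  for (j in seq_along(b)) {
    idx <- seq_along(a) + j - 1L
    keep <- idx <= n_max
    out[idx[keep]] <- out[idx[keep]] + a[keep] * b[j]
  }
  out
}

#' Construct an isotope pattern object
#'
#' @param offset Mass offsets from the monoisotopic peak in Da; first must
#'   be 0, strictly increasing.
#' @param abundance Relative abundances; first must be 1, all >= 0.
#' @return An `isotope_pattern` data frame.
#' @export
isotope_pattern <- function(offset, abundance) {
  stopifnot(length(offset) == length(abundance), length(offset) >= 1)
  if (offset[1] != 0 || abs(abundance[1] - 1) > 1e-9)
    stop("first isotope peak must be the monoisotopic peak (offset 0, abundance 1)")
  if (any(diff(offset) <= 0)) stop("offsets must be strictly increasing")
  if (any(abundance < 0)) stop("abundances must be non-negative")
  structure(data.frame(offset = offset, abundance = abundance),
            class = c("isotope_pattern", "data.frame"))
}

# A+k/A ratio from a pattern, 0 when the peak is absent.
.iso_ratio <- function(pattern, k) {
  i <- which(abs(pattern$offset - k) < 0.4)
  if (!length(i)) 0 else pattern$abundance[i[1]] / pattern$abundance[1]
}

#' Estimate the chlorine count from an observed isotope pattern
#'
#' Compares the observed A+2/A abundance ratio against theoretical ratios for
#' 0-3 chlorines and returns the closest. When the best and second-best
#' candidates lie within `tolerance` of each other the A+4/A ratio breaks the
#' tie if available, and the result is flagged low-confidence.
#'
#' @param observed An `isotope_pattern` (offsets in Da from monoisotopic).
#' @param tolerance Relative-abundance tolerance for the ambiguity flag.
#' @param max_cl Largest chlorine count considered.
#' @param skeleton Optional formula (string or counts) for the chlorine-free
#'   part of the molecule, refining the theoretical ratios with its 13C2 etc.
#'   contribution.
#' @return List with `count` (integer) and `low_confidence` (logical).
#' @export
estimate_chlorine_count <- function(observed, tolerance = 0.05, max_cl = 3L,
                                    skeleton = NULL) {
  stopifnot(nrow(observed) >= 1)
  obs2 <- .iso_ratio(observed, 2)
  obs4 <- .iso_ratio(observed, 4)
  base <- if (is.null(skeleton)) integer(0) else .as_counts(skeleton)
  theo <- vapply(0:max_cl, function(k) {
    f <- base
    if (k > 0) f["Cl"] <- (if ("Cl" %in% names(f)) f[["Cl"]] else 0L) + k
    if (!length(f)) return(c(0, 0))
    p <- simulate_isotope_pattern(f, n_peaks = 5L)
    c(.iso_ratio(p, 2), .iso_ratio(p, 4))
  }, numeric(2))
  err2 <- abs(obs2 - theo[1, ])
  ord <- order(err2)
  best <- ord[1]
  ambiguous <- length(ord) > 1 && (err2[ord[2]] - err2[best]) < tolerance
  if (ambiguous && obs4 > 0) {
    # tie-break on A+4 among the two closest candidates
    pair <- ord[1:2]
    best <- pair[which.min(abs(obs4 - theo[2, pair]))]
  }
  list(count = best - 1L, low_confidence = ambiguous)
}

# Ring-double-bond equivalents of an (ionic) composition; even-electron ions
# give half-integer values. Chemically impossible below -0.5.
.rdbe <- function(counts) {
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  g("C") + 1 - (g("H") + g("F") + g("Cl") + g("Br")) / 2 + (g("N") + g("P")) / 2
}

#' Enumerate subformulas of a precursor ion matching a target m/z
#'
#' Exhaustively searches the lattice of elemental compositions element-wise
#' bounded by the precursor ion composition for fragments whose ionic m/z lies
#' within `tol_ppm` of `target_mz`. Chemically impossible candidates
#' (ring-double-bond equivalents < `rdbe_min`) are pruned. Used as a local
#' fragment-plausibility check in place of online in-silico services.
#'
#' @param precursor Ionic elemental composition of the precursor (string or
#'   named counts), e.g. the protonated molecule for positive mode.
#' @param target_mz Observed fragment m/z in Th.
#' @param charge Fragment charge, +1 or -1 (normally the precursor's).
#' @param tol_ppm Mass tolerance in ppm.
#' @param rdbe_min Minimum ring-double-bond equivalents (default -0.5).
#' @return Data frame with columns `formula`, `mz`, `error_ppm`, sorted by
#'   absolute mass error; zero rows when nothing matches.
#' @examples
#' enumerate_subformulas("C4H5ClN3O", 100.99010, charge = 1)
#' @export
enumerate_subformulas <- function(precursor, target_mz, charge = 1L,
                                  tol_ppm = 5, rdbe_min = -0.5) {
  stopifnot(tol_ppm > 0)
  bounds <- .as_counts(precursor)
  tol_da <- target_mz * tol_ppm * 1e-6
  e_corr <- -charge * .ELECTRON_MASS
  lo <- target_mz - tol_da - e_corr   # neutral-composition mass window
  hi <- target_mz + tol_da - e_corr
  syms <- names(bounds)
  masses <- .ELEMENT_MASS[syms]
  # depth-first over elements with remaining-mass pruning
  hits <- list()
  rec <- function(i, acc, mass) {
    if (mass > hi) return(invisible())
    if (i > length(syms)) {
      if (mass >= lo && mass <= hi && sum(acc) > 0) {
        cand <- acc[acc > 0L]
        if (.rdbe(cand) >= rdbe_min)
          hits[[length(hits) + 1L]] <<- cand
      }
      return(invisible())
    }
    for (n in 0:bounds[[i]]) {
      acc[syms[i]] <- n
      rec(i + 1L, acc, mass + n * masses[[i]])
    }
  }
  rec(1L, stats::setNames(integer(length(syms)), syms), 0)
  if (!length(hits)) {
    return(data.frame(formula = character(0), mz = numeric(0),
                      error_ppm = numeric(0), stringsAsFactors = FALSE))
  }
  mz <- vapply(hits, function(h) ion_mz(h, charge = charge), numeric(1))
  err <- (mz - target_mz) / target_mz * 1e6
  out <- data.frame(
    formula = vapply(hits, format_formula, character(1)),
    mz = mz, error_ppm = err, stringsAsFactors = FALSE
  )
  out[order(abs(out$error_ppm)), , drop = FALSE]
}
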