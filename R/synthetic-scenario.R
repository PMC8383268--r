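# Seeded synthetic datasets with the statistical structure the screening
# workflow assumes, plus ground truth: two sites, two four-week campaigns,
# both ionization polarities, TPs spiked at known concentrations, parents
# with realistic application/detection histories, decoy features.

#' Scenario configuration
#'
#' Defaults mirror the study design being emulated: two sampling sites in
#' agricultural streams, two campaigns of four weekly composite samples each,
#' screening in both electrospray polarities. Compound counts are kept at a
#' scale where every stage remains inspectable; areas carry multiplicative
#' (log-normal) noise as LC-MS responses do.
#'
#' @param seed Integer seed fixing every random draw.
#' @param sites Site ids.
#' @param campaign_starts ISO dates of the first sampled week per campaign.
#' @param n_weeks Weekly samples per campaign.
#' @param n_target_parents,n_additional_parents Registry composition.
#' @param metabolites_per_parent Key metabolites listed per parent.
#' @param n_spiked_tps Number of TPs truly present.
#' @param spike_concentrations Pool of true concentrations (ug/L) sampled per
#'   spiked TP; defaults are the midpoints of the reporting ranges plus a
#'   below-range level.
#' @param noise_cv Coefficient of variation of the multiplicative area noise.
#' @param frac_library Fraction of TPs with a spectral-library record.
#' @param frac_applied Fraction of parents with application events per site.
#' @param frac_standards Fraction of spiked TPs with a reference standard.
#' @param n_decoys Decoy features per site/week/polarity.
#' @param mz_jitter_ppm SD of the mass-accuracy jitter applied to feature m/z.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            sites = c("E", "M"),
                            campaign_starts = c("2017-05-01", "2017-09-04"),
                            n_weeks = 4L,
                            n_target_parents = 12L,
                            n_additional_parents = 4L,
                            metabolites_per_parent = 2L,
                            n_spiked_tps = 8L,
                            spike_concentrations = c(0.05, 0.3, 3, 30),
                            noise_cv = 0.1,
                            frac_library = 0.6,
                            frac_applied = 0.7,
                            frac_standards = 0.6,
                            n_decoys = 15L,
                            mz_jitter_ppm = 1) {
  cfg <- list(seed = as.integer(seed), sites = sites,
              campaign_starts = as.Date(campaign_starts),
              n_weeks = as.integer(n_weeks),
              n_target_parents = as.integer(n_target_parents),
              n_additional_parents = as.integer(n_additional_parents),
              metabolites_per_parent = as.integer(metabolites_per_parent),
              n_spiked_tps = as.integer(n_spiked_tps),
              spike_concentrations = spike_concentrations,
              noise_cv = noise_cv, frac_library = frac_library,
              frac_applied = frac_applied, frac_standards = frac_standards,
              n_decoys = as.integer(n_decoys), mz_jitter_ppm = mz_jitter_ppm)
  stopifnot(cfg$n_weeks >= 1, cfg$noise_cv >= 0, cfg$n_decoys >= 0)
  structure(cfg, class = "scenario_config")
}

# RNG fixed across platforms/versions for byte-identical scenario output.
.with_scenario_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.random_parent_formula <- function() {
  c_n <- sample(8:18, 1)
  counts <- c(C = c_n, H = c_n + sample(0:c_n, 1),
              N = sample(0:3, 1), O = sample(1:4, 1),
              Cl = sample(0:2, 1, prob = c(0.5, 0.3, 0.2)))
  counts[counts > 0]
}

.derive_tp_formula <- function(parent_counts) {
  f <- parent_counts
  dc <- sample(1:3, 1)
  f["C"] <- max(4L, f[["C"]] - dc)
  if ("H" %in% names(f)) f["H"] <- max(5L, f[["H"]] - sample(0:4, 1))
  # oxidative transformations commonly add oxygen
  if (stats::runif(1) < 0.5)
    f["O"] <- (if ("O" %in% names(f)) f[["O"]] else 0L) + 1L
  f[f > 0]
}

.gaussian_trace <- function(rt, height, n = 20, width = 0.1, noise_frac = 0.01) {
  t <- seq(rt - 3 * width, rt + 3 * width, length.out = n)
  y <- height * exp(-(t - rt)^2 / (2 * width^2)) +
    abs(stats::rnorm(n, 0, noise_frac * height)) + 1
  cbind(t, y)
}

.observed_isotope <- function(formula, rel_noise = 0.01) {
  p <- simulate_isotope_pattern(formula, n_peaks = 5L)
  ab <- p$abundance * exp(stats::rnorm(nrow(p), 0, rel_noise))
  ab[1] <- 1
  cbind(p$offset, ab)
}

#' Generate a complete synthetic screening scenario
#'
#' Writes every input the pipeline consumes — registry, key-metabolite table,
#' feature table, MSP spectral library, monitoring metadata, RT calibrants,
#' hydrophobicity descriptors, internal-standard areas, matrix-matched
#' calibration data, reference standards — plus a ground-truth table, all
#' deterministic under the configured seed. Feature m/z values sit within the
#' configured jitter of theory, traces are Gaussian, isotope clusters match
#' the formula's chlorine count, MS2 spectra are drawn from the library
#' record when one exists, and areas are proportional to true concentration
#' with log-normal noise.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (ground-truth data frame) and `suspects` (the generated suspect list).
#' @export
generate_scenario <- function(config = scenario_config(), dir = tempfile("scenario")) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .with_scenario_seed(config$seed, .generate_scenario_impl(config, dir))
}

.generate_scenario_impl <- function(config, dir) {
  weeks <- as.Date(unlist(lapply(config$campaign_starts, function(d)
    as.list(d + 7 * (seq_len(config$n_weeks) - 1)))), origin = "1970-01-01")
  sample_date <- max(weeks)

  ## registry + metabolites ---------------------------------------------
  n_par <- config$n_target_parents + config$n_additional_parents
  registry <- data.frame(
    compound_id = sprintf("P%03d", seq_len(n_par)),
    name = sprintf("parent-%03d", seq_len(n_par)),
    formula = vapply(seq_len(n_par),
                     function(i) format_formula(.random_parent_formula()),
                     character(1)),
    role = rep(c("monitored_target", "additional_parent"),
               c(config$n_target_parents, config$n_additional_parents)),
    addition_category = c(rep(NA_character_, config$n_target_parents),
                          sample(c("newly_registered", "seed_treatment",
                                   "tp_only_monitored_parent",
                                   "special_concern"),
                                 config$n_additional_parents, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  registry$registered_sites <- vapply(seq_len(n_par), function(i) {
    s <- config$sites[stats::runif(length(config$sites)) < 0.8]
    paste(s, collapse = ";")
  }, character(1))

  met_rows <- list()
  for (i in seq_len(n_par)) {
    pf <- parse_formula(registry$formula[i])
    k_parent <- round(stats::rlnorm(1, log(2000), 1.2), 1)
    for (j in seq_len(config$metabolites_per_parent)) {
      tpf <- .derive_tp_formula(pf)
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        parent_id = registry$compound_id[i],
        tp_id = sprintf("TP-%03d-%d", i, j),
        tp_name = sprintf("parent-%03d-TP%d", i, j),
        formula = format_formula(tpf),
        k_foc = if (stats::runif(1) < 0.7)
          round(k_parent * stats::rlnorm(1, -1, 0.8), 1) else NA_real_,
        parent_k_foc = k_parent,
        stringsAsFactors = FALSE)
    }
  }
  metabolites <- do.call(rbind, met_rows)
  suspects <- build_suspect_list(registry, metabolites)

  ## descriptors, retention line, polarities ----------------------------
  descriptors <- data.frame(
    suspect_id = suspects$suspect_id,
    descriptor = round(stats::runif(nrow(suspects), 0.5, 6), 3),
    stringsAsFactors = FALSE)
  rt_true <- stats::setNames(1 + 1.8 * descriptors$descriptor,
                             descriptors$suspect_id)
  # targets double as RT calibrants (standards available from monitoring)
  targets <- suspects$suspect_id[suspects$origin == "target"]
  rt_cal <- data.frame(
    compound_id = targets,
    descriptor = descriptors$descriptor[match(targets, descriptors$suspect_id)],
    rt = round(rt_true[targets] + stats::rnorm(length(targets), 0, 0.05), 4),
    stringsAsFactors = FALSE)

  tps <- non_target_subset(suspects, tp_only = TRUE)
  pol_pref <- stats::setNames(
    ifelse(stats::runif(nrow(suspects)) < 0.55, "positive", "negative"),
    suspects$suspect_id)

  ## spectral library ---------------------------------------------------
  lib_tp <- tps$suspect_id[stats::runif(nrow(tps)) < config$frac_library]
  library_records <- list()
  for (id in lib_tp) {
    s <- suspects[suspects$suspect_id == id, ]
    pol <- pol_pref[[id]]
    adduct <- if (pol == "positive") "[M+H]+" else "[M-H]-"
    charge <- if (pol == "positive") 1L else -1L
    prec <- .as_counts(s$formula)
    prec["H"] <- prec[["H"]] + charge
    n_frag <- sample(3:5, 1)
    frags <- list()
    guard <- 0
    while (length(frags) < n_frag && guard < 200) {
      guard <- guard + 1
      sub <- vapply(prec, function(n) sample(0:n, 1), integer(1))
      sub <- sub[sub > 0]
      if (!length(sub) || !"C" %in% names(sub)) next
      if (sum(sub) < 4 || identical(sub[names(prec)], prec)) next
      if (.rdbe(sub) < -0.5) next
      mz <- ion_mz(sub, charge = charge)
      if (mz < 50) next
      frags[[length(frags) + 1L]] <- mz
    }
    if (length(frags) < 2) next
    mzs <- sort(unlist(frags))
    library_records[[length(library_records) + 1L]] <- list(
      name = s$name, formula = s$formula, adduct = adduct,
      precursor_mz = if (pol == "positive") s$mz_pos else s$mz_neg,
      peaks = cbind(mzs, round(stats::runif(length(mzs), 20, 100), 1)),
      diagnostic = seq_along(mzs) %in%
        sample(seq_along(mzs), min(2L, length(mzs))),
      warning = "")
  }
  lib_names <- vapply(library_records, `[[`, character(1), "name")

  ## spike plan + monitoring --------------------------------------------
  n_spike <- min(config$n_spiked_tps, nrow(tps))
  spiked <- sample(tps$suspect_id, n_spike)
  spike_conc <- stats::setNames(
    sample(config$spike_concentrations, n_spike, replace = TRUE), spiked)
  spike_site <- stats::setNames(
    sample(config$sites, n_spike, replace = TRUE), spiked)

  # parents of spiked TPs must show use at the spike site (rescue pathway)
  must_apply <- unique(do.call(rbind, lapply(spiked, function(id) {
    ps <- strsplit(suspects$parent_ids[suspects$suspect_id == id], ";")[[1]]
    data.frame(parent = ps, site = spike_site[[id]], stringsAsFactors = FALSE)
  })))
  app_rows <- det_rows <- list()
  for (p in registry$compound_id) {
    for (s in config$sites) {
      applied <- stats::runif(1) < config$frac_applied ||
        any(must_apply$parent == p & must_apply$site == s)
      if (applied) {
        app_rows[[length(app_rows) + 1L]] <- data.frame(
          site = s, date = as.character(sample_date - sample(30:2000, 1)),
          compound_id = p, dose = round(stats::runif(1, 50, 2000), 1),
          stringsAsFactors = FALSE)
        if (stats::runif(1) < 0.8) {
          wk <- sample(weeks, sample(1:4, 1))
          det_rows[[length(det_rows) + 1L]] <- data.frame(
            site = s, week = as.character(wk), compound_id = p,
            concentration = round(stats::rlnorm(length(wk), log(0.05), 1), 4),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  applications <- do.call(rbind, app_rows)
  detections <- do.call(rbind, det_rows)

  ## features ------------------------------------------------------------
  rf <- stats::setNames(stats::rlnorm(nrow(suspects), log(1e5), 0.3),
                        suspects$suspect_id)
  is_area_val <- 5e4
  feat_rows <- list()
  truth_rows <- list()
  fid <- 0L
  for (id in spiked) {
    s <- suspects[suspects$suspect_id == id, ]
    pol <- pol_pref[[id]]
    both <- stats::runif(1) < 0.15
    pols <- if (both) c("positive", "negative") else pol
    site <- spike_site[[id]]
    conc <- spike_conc[[id]]
    lib_i <- match(s$name, lib_names)
    for (wk in as.list(weeks)) {
      for (pp in pols) {
        fid <- fid + 1L
        mz_theo <- if (pp == "positive") s$mz_pos else s$mz_neg
        mz_obs <- mz_theo * (1 + stats::rnorm(1, 0, config$mz_jitter_ppm) * 1e-6)
        rt_obs <- rt_true[[id]] + stats::rnorm(1, 0, 0.05)
        area <- rf[[id]] * conc *
          (if (config$noise_cv > 0)
             stats::rlnorm(1, -0.5 * log(1 + config$noise_cv^2),
                           sqrt(log(1 + config$noise_cv^2))) else 1)
        ms2 <- matrix(numeric(0), ncol = 2)
        if (!is.na(lib_i)) {
          pk <- library_records[[lib_i]]$peaks
          ms2 <- cbind(pk[, 1] * (1 + stats::rnorm(nrow(pk), 0, 2e-6)),
                       pk[, 2] * exp(stats::rnorm(nrow(pk), 0, 0.1)))
        }
        feat_rows[[fid]] <- list(
          feature_id = sprintf("F%05d", fid), site = site,
          week = as.character(wk), polarity = pp, mz = mz_obs, rt = rt_obs,
          area = area,
          trace = .gaussian_trace(rt_obs, area / 100),
          isotope = .observed_isotope(s$formula),
          ms2 = ms2)
      }
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      suspect_id = id, name = s$name, site = site,
      polarity = paste(sort(pols), collapse = ";"),
      concentration = conc,
      true_range = .true_range(conc),
      has_library = !is.na(lib_i),
      stringsAsFactors = FALSE)
  }

  for (s in config$sites) for (wk in as.list(weeks))
    for (pp in c("positive", "negative")) {
      for (d in seq_len(config$n_decoys)) {
        fid <- fid + 1L
        mz <- stats::runif(1, 80, 600)
        rt <- stats::runif(1, 0.5, 12)
        h <- stats::rlnorm(1, log(2e4), 1)
        feat_rows[[fid]] <- list(
          feature_id = sprintf("F%05d", fid), site = s,
          week = as.character(wk), polarity = pp, mz = mz, rt = rt, area = h,
          trace = .gaussian_trace(rt, h / 100),
          isotope = cbind(0:1, c(1, stats::runif(1, 0.02, 0.2))),
          ms2 = matrix(numeric(0), ncol = 2))
      }
    }

  features <- data.frame(
    feature_id = vapply(feat_rows, `[[`, character(1), "feature_id"),
    site = vapply(feat_rows, `[[`, character(1), "site"),
    week = vapply(feat_rows, `[[`, character(1), "week"),
    polarity = vapply(feat_rows, `[[`, character(1), "polarity"),
    mz = vapply(feat_rows, `[[`, numeric(1), "mz"),
    rt = vapply(feat_rows, `[[`, numeric(1), "rt"),
    area = vapply(feat_rows, `[[`, numeric(1), "area"),
    stringsAsFactors = FALSE)
  features$trace <- lapply(feat_rows, `[[`, "trace")
  features$isotope <- lapply(feat_rows, `[[`, "isotope")
  features$ms2 <- lapply(feat_rows, `[[`, "ms2")

  ## internal standards, calibration, reference standards ---------------
  is_df <- expand.grid(site = config$sites, week = as.character(weeks),
                       polarity = c("positive", "negative"),
                       stringsAsFactors = FALSE)
  is_df$is_area <- is_area_val
  cal_rows <- list()
  for (id in tps$suspect_id) for (s in config$sites) {
    lv <- c(0.1, 1, 10)
    cal_rows[[length(cal_rows) + 1L]] <- data.frame(
      compound_id = id, site = s, level = lv,
      area = rf[[id]] * lv *
        exp(stats::rnorm(3, 0, 0.05)),
      is_area = is_area_val, blank_area = 0, blank_is_area = is_area_val,
      stringsAsFactors = FALSE)
  }
  calibration <- do.call(rbind, cal_rows)

  std_ids <- spiked[stats::runif(n_spike) < config$frac_standards]
  std_rows <- list()
  for (id in std_ids) {
    s <- suspects[suspects$suspect_id == id, ]
    lib_i <- match(s$name, lib_names)
    ms2 <- if (!is.na(lib_i)) library_records[[lib_i]]$peaks
           else cbind(s$neutral_mass * c(0.4, 0.7), c(100, 60))
    std_rows[[length(std_rows) + 1L]] <- data.frame(
      suspect_id = id, rt = round(rt_true[[id]], 4),
      ms2 = .encode_pairs(ms2), stringsAsFactors = FALSE)
  }
  standards <- if (length(std_rows)) do.call(rbind, std_rows)
    else data.frame(suspect_id = character(0), rt = numeric(0),
                    ms2 = character(0), stringsAsFactors = FALSE)

  truth <- do.call(rbind, truth_rows)

  ## write everything ----------------------------------------------------
  paths <- list(
    registry = file.path(dir, "registry.csv"),
    metabolites = file.path(dir, "metabolites.csv"),
    features = file.path(dir, "features.csv"),
    library = file.path(dir, "library.msp"),
    applications = file.path(dir, "applications.csv"),
    detections = file.path(dir, "detections.csv"),
    rt_calibrants = file.path(dir, "rt_calibrants.csv"),
    descriptors = file.path(dir, "descriptors.csv"),
    internal_standards = file.path(dir, "internal_standards.csv"),
    calibration = file.path(dir, "calibration.csv"),
    standards = file.path(dir, "standards.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.json"))
  utils::write.csv(registry, paths$registry, row.names = FALSE, na = "")
  utils::write.csv(metabolites, paths$metabolites, row.names = FALSE, na = "")
  write_feature_table(features, paths$features)
  write_spectral_library(library_records, paths$library)
  utils::write.csv(applications, paths$applications, row.names = FALSE)
  utils::write.csv(detections, paths$detections, row.names = FALSE)
  utils::write.csv(rt_cal, paths$rt_calibrants, row.names = FALSE)
  utils::write.csv(descriptors, paths$descriptors, row.names = FALSE)
  utils::write.csv(is_df, paths$internal_standards, row.names = FALSE)
  utils::write.csv(calibration, paths$calibration, row.names = FALSE)
  utils::write.csv(standards, paths$standards, row.names = FALSE)
  utils::write.csv(truth, paths$ground_truth, row.names = FALSE)
  cfg_out <- unclass(config)
  cfg_out$campaign_starts <- as.character(cfg_out$campaign_starts)
  jsonlite::write_json(c(cfg_out, lapply(paths, identity)),
                       paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, suspects = suspects,
                 sample_date = sample_date))
}

.true_range <- function(conc) {
  if (conc < 0.1) "<0.1" else if (conc < 1) "0.1-1"
  else if (conc < 10) "1-10" else ">10"
}

#' Fixture reproducing the published workflow accounting
#'
#' Constructs, in memory, the candidate set whose retention, deduplication
#' and confirmation arithmetic matches the published screening study:
#' 114 candidates entering the monitoring stage (23 with strong/moderate
#' chemical evidence, 91 weak of which 19 have monitoring support), so that
#' retention yields 42; 4 of the 38 distinct structures among the retained
#' occur in both polarities; and reference standards for 26 of the 38, 11 of
#' which are constructed to match (rt and fragments) and 15 to fail. This is
#' a structural check of the decision rules against printed arithmetic, not
#' a re-analysis of raw data.
#'
#' @return List with `hits` (data frame: `suspect_id`, `polarity`, `tier`,
#'   `confidence_level`, `rt`, and list-column `ms2`), `evidence` (list of
#'   `monitoring_evidence`, one per hit) and `standards` (named list of
#'   `rt` + `ms2` per suspect with a purchased standard).
#' @export
paper_shape_fixture <- function() {
  ev <- function(applied, detected = FALSE, plaus = "neutral") {
    structure(list(
      parent_registered_at_site = applied,
      parent_applied_at_site = applied,
      last_application_date = if (applied) as.Date("2014-05-15") else as.Date(NA),
      parent_detected_at_site = detected,
      parent_detection_weeks = as.Date(character(0)),
      mobility_flag = NA, source_plausibility = plaus),
      class = "monitoring_evidence")
  }
  hits <- list(); evid <- list()
  add <- function(id, pol, tier, level, applied, detected = FALSE) {
    hits[[length(hits) + 1L]] <<- data.frame(
      suspect_id = id, polarity = pol, tier = tier,
      confidence_level = level, rt = 5, stringsAsFactors = FALSE)
    evid[[length(evid) + 1L]] <<- ev(applied, detected)
  }
  # 38 unique structures among the retained; 4 detected in both polarities.
  # Structures 1..19: strong/moderate evidence (23 hits incl. the 4 duals).
  for (i in 1:19) {
    pol <- if (i %% 2) "positive" else "negative"
    tier <- if (i <= 12) "strong" else "moderate"
    level <- if (i <= 6) "2a" else if (i <= 12) "2b" else "3"
    add(sprintf("S%02d", i), pol, tier, level, applied = TRUE, detected = TRUE)
    if (i <= 4)  # dual-polarity detections
      add(sprintf("S%02d", i),
          if (pol == "positive") "negative" else "positive",
          tier, level, applied = TRUE, detected = TRUE)
  }
  # Structures 20..38: weak chemistry, rescued by monitoring (19 hits).
  for (i in 20:38)
    add(sprintf("S%02d", i), if (i %% 2) "negative" else "positive",
        "weak", if (i %% 3) "4" else "5", applied = TRUE)
  # 72 weak candidates with no monitoring support: discarded (114 total in).
  for (i in 39:110)
    add(sprintf("D%03d", i), if (i %% 2) "positive" else "negative",
        "weak", "5", applied = FALSE)
  hits_df <- do.call(rbind, hits)
  frag <- function(k) cbind(c(100 + k, 150 + k, 200 + k), c(100, 60, 30))
  hits_df$ms2 <- lapply(seq_len(nrow(hits_df)), function(i) {
    id_num <- suppressWarnings(as.integer(sub("^[SD]", "", hits_df$suspect_id[i])))
    frag(id_num %% 50)
  })
  # standards for 26 of the 38 unique structures; 11 constructed to match
  standards <- list()
  for (i in 1:26) {
    id <- sprintf("S%02d", i)
    if (i <= 11) standards[[id]] <- list(rt = 5, ms2 = frag(i %% 50))
    else standards[[id]] <- list(rt = 5, ms2 = frag(i %% 50) + 5)  # no overlap
  }
  list(hits = hits_df, evidence = evid, standards = standards)
}
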