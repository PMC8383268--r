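# Independent oracles, deliberately implemented differently from the package:
# a separate monoisotopic mass table and a vectorized expand.grid brute force
# for subformula enumeration.

ORACLE_MASS <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371
)
ORACLE_ELECTRON <- 0.00054857990907

oracle_mass <- function(counts) {
  if (!length(counts)) return(0)
  sum(counts * ORACLE_MASS[names(counts)])
}

oracle_ion_mz <- function(counts, charge) {
  oracle_mass(counts) - charge * ORACLE_ELECTRON
}

# nested-loop brute force over the bounded composition lattice
oracle_subformulas <- function(bounds, target_mz, charge, tol_ppm,
                               rdbe_min = -0.5) {
  grid <- do.call(expand.grid, lapply(bounds, function(n) 0:n))
  names(grid) <- names(bounds)
  mass <- as.matrix(grid) %*% ORACLE_MASS[names(bounds)]
  mz <- mass - charge * ORACLE_ELECTRON
  g <- function(el) if (el %in% names(grid)) grid[[el]] else 0
  rdbe <- g("C") + 1 - (g("H") + g("F") + g("Cl") + g("Br")) / 2 +
    (g("N") + g("P")) / 2
  ok <- abs(mz - target_mz) <= target_mz * tol_ppm * 1e-6 &
    rowSums(grid) > 0 & rdbe >= rdbe_min
  apply(grid[ok, , drop = FALSE], 1, function(r) {
    r <- r[r > 0]
    tpscreen::format_formula(stats::setNames(as.integer(r), names(r)))
  })
}

random_formula <- function(max_c = 20) {
  counts <- c(C = sample(1:max_c, 1), H = sample(1:(2 * max_c), 1),
              N = sample(0:3, 1), O = sample(0:5, 1),
              S = sample(0:1, 1), Cl = sample(0:3, 1))
  counts[counts > 0]
}

# registry + metabolite fixture with a given composition and all-distinct
# structures (unique formulas by construction)
make_registry_fixture <- function(n_targets, n_additional,
                                  n_target_mets, n_additional_mets) {
  n_par <- n_targets + n_additional
  registry <- data.frame(
    compound_id = sprintf("P%03d", seq_len(n_par)),
    name = sprintf("parent-%03d", seq_len(n_par)),
    formula = sprintf("C%dH%dNO2", 10 + seq_len(n_par), 12 + seq_len(n_par)),
    role = rep(c("monitored_target", "additional_parent"),
               c(n_targets, n_additional)),
    addition_category = c(rep(NA_character_, n_targets),
                          rep("seed_treatment", n_additional)),
    registered_sites = "E;M",
    stringsAsFactors = FALSE)
  met <- function(n, parents, tag) {
    if (!n) return(data.frame(
      parent_id = character(0), tp_id = character(0), tp_name = character(0),
      formula = character(0), k_foc = numeric(0), parent_k_foc = numeric(0),
      stringsAsFactors = FALSE))
    data.frame(
      parent_id = parents[((seq_len(n) - 1) %% length(parents)) + 1],
      tp_id = sprintf("%s-%03d", tag, seq_len(n)),
      tp_name = sprintf("%s-met-%03d", tag, seq_len(n)),
      formula = sprintf("C%dH%dN%dO3", 4 + seq_len(n), 6 + seq_len(n),
                        if (tag == "TPA") 2L else 1L),
      k_foc = NA_real_, parent_k_foc = NA_real_,
      stringsAsFactors = FALSE)
  }
  metabolites <- rbind(
    met(n_target_mets, registry$compound_id[seq_len(n_targets)], "TPT"),
    met(n_additional_mets,
        registry$compound_id[n_targets + seq_len(n_additional)], "TPA"))
  list(registry = registry, metabolites = metabolites)
}

small_scenario_config <- function(seed) {
  tpscreen::scenario_config(
    seed = seed, n_target_parents = 6L, n_additional_parents = 2L,
    n_spiked_tps = 4L, n_decoys = 5L)
}
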