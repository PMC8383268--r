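---
title: "Monitoring-integrated suspect screening of pesticide TPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring-integrated suspect screening of pesticide TPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpscreen)
```

## The problem and the workflow

Regulatory water monitoring quantifies parent pesticides against reference
standards, but transformation products (TPs) formed in soil and water are
rarely covered: standards are missing, spectral libraries are sparse, and
many TPs are absent even from the large chemical databases that in-silico
identification tools rely on. Suspect screening bridges this gap — features
from high-resolution mass spectrometry are matched against a list of
*expected* compounds — but with weak MS2 evidence the conventional workflow
discards most TP candidates.

`tpscreen` implements a two-step workflow. The first step is conventional
chemical evidence: exact-mass matching, peak-shape and retention-plausibility
gates, and fragment scoring. The second step folds in what a national
monitoring program already knows: where each parent pesticide is registered,
when it was last applied, whether it has been detected at the site, and how
mobile the TP is relative to its parent (K_foc, the organic-carbon–water
partitioning coefficient in mL/g; smaller means more mobile). Monitoring
knowledge is used *additively*: it can rescue a weak-evidence candidate whose
parent is demonstrably present or in use at the site, but it never discards
a candidate with solid chemical evidence — if the source is implausible the
hit is only annotated with a source warning, because "the structure is X"
and "X came from pesticide Y at this field" are separate claims.

## Suspect-list assembly

The list combines four blocks: all monitored target compounds; their key
metabolites (TPs flagged as significant in regulatory authorization
documents); additional parents of monitoring interest (newly registered
compounds, seed treatments, parents whose TP is already monitored, compounds
of special concern); and the key metabolites of those additional parents.
Each entry carries its neutral monoisotopic mass and the expected m/z in both
polarities, computed from the formula, so a stored list can be re-validated
on load. A metabolite listed under several parents (a real case: phthalic
acid is a degradate of several actives) is collapsed to one entry with
merged parent links; the collapse can be disabled to reproduce raw counts.

## Mass arithmetic and fragment plausibility

All m/z values are exact sums of monoisotopic atomic masses (IUPAC, six
decimals). Adduct m/z adds or subtracts the proton mass 1.00727646 Da; ionic
compositions subtract charge × electron mass (0.00054858 Da). The electron
term matters: published diagnostic fragments are only reproduced at the
fifth decimal with it included.

Fragment plausibility replaces online in-silico services with a local,
exhaustive subformula enumeration: every elemental composition element-wise
bounded by the precursor ion composition whose ion m/z falls within
tolerance, pruned by a ring-double-bond-equivalent filter (RDBE ≥ −0.5,
the standard bound below which no valence-consistent structure exists).
The search is depth-first with remaining-mass pruning and is tested for set
equality against a naive nested-loop enumeration.

Isotope patterns are simulated at unit-mass-offset resolution by convolving
per-element isotopologue distributions; this coarse resolution is sufficient
because the only pattern feature used downstream is the A+2/A ratio, which
is ≈ 0.32 per chlorine and dominates every other contribution. Chlorine
counting picks the k ∈ {0..3} whose theoretical ratio is closest to the
observed one, uses A+4 as a tie-breaker, and flags the result low-confidence
when the two best candidates are within tolerance.

## Evidence tiers, retention, and confidence levels

Fragment evidence is summarized in three tiers. *Strong*: at least two
diagnostic fragments matched, or at least two library fragments with ≥ 80 %
of observed fragments subformula-plausible. *Moderate*: exactly one
diagnostic/library match with ≥ 50 % plausible. *Weak*: everything else,
including an empty MS2 spectrum. The two-diagnostic-fragment threshold
mirrors how identification cases are argued in practice: two independent
structure-specific product ions are treated as conclusive spectral evidence,
one as supporting.

Retention: strong and moderate candidates are always kept; weak candidates
are kept only when the parent was applied or detected at the site within the
lookback window. The lookback default is 10 years — TPs of chloridazon-type
persistence are found years after the last application, so a short window
would defeat the purpose; 10 years covers the documented
application-to-detection gaps while still excluding legacy compounds.

Confidence levels follow the ordinal 1/2a/2b/3/4/5 scale: 2a for a full
library-spectrum match, 2b for ≥ 2 diagnostic fragments without one, 3 for
exactly one supporting fragment, 4 for no usable fragments but an
unequivocal molecular formula, 5 for exact mass only, and 1 reserved for
reference-standard confirmation (RT within tolerance and ≥ 2 standard
fragments recovered). "Formula unequivocal" is operationalized as: exactly
one suspect-list formula fits the accurate mass at MS1 tolerance *and* the
observed isotope cluster's chlorine count matches that formula. The mapping
from evidence combinations to 2a/2b/3 is a formalization choice — the scale's
verbal definitions leave room — and is kept deliberately monotone: adding a
matched fragment can never worsen a level (a property the tests enforce).

## Semiquantification

Concentrations are reported as ordinal ranges, not point values, reflecting
quantification without method validation. The matrix-matched calibration
uses levels 0.1, 1 and 10 µg/L; responses are internal-standard-normalized
(one IS per polarity) and blank-subtracted, and a least-squares line is fit.
Two fallbacks: if the curve shows no linearity (R² < 0.98 or non-positive
slope — the threshold is configurable; 0.98 is a common acceptance value for
a 3-point environmental calibration) the compound is reported only as
`detected`; if the 0.1 µg/L point was not detected, estimates below 1 µg/L
are reported as `<1`. Binning is left-closed/right-open ([0.1, 1), [1, 10),
[10, ∞)), so an estimate of exactly 1.0 falls in `1–10`; the printed range
notation is ambiguous on this point and a convention had to be fixed.
Negative estimates (possible with a nonzero intercept) truncate to `<0.1`
with an audit warning. A solvent calibration, where available, is loaded but
unused by default: its role in range assignment is unspecified, and
matrix-matched curves are the defensible basis for ranges in matrix.

## Gate thresholds

None of the peak-shape/RT criteria have published values; the defaults in
`screening_defaults()` are field conventions, all configurable: MS1 5 ppm,
MS2 10 ppm or 5 mDa (whichever is larger), ≥ 7 points across the peak,
half-width asymmetry within [0.5, 2], SNR ≥ 3 (noise estimated as the
residual about a 3-point running mean, which is robust to the peak's own
slope), RT window ±3 residual SDs around a linear hydrophobicity-descriptor
model with ≥ 5 calibrants. The descriptor (e.g. an estimated log
partition coefficient) is an input column, never computed internally. A
missing descriptor yields RT plausibility `unknown`, which is *not* a
failure — missing data must not silently discard candidates.

## What the synthetic scenarios emulate — and what they do not

`generate_scenario()` reproduces the statistical structure the workflow
assumes: two sites, two campaigns of four weekly samples, both polarities;
spiked TPs whose feature m/z lies within 1 ppm of theory; Gaussian
chromatographic traces; isotope clusters consistent with the formula's
chlorine count; MS2 spectra drawn from the library record when one exists;
areas proportional to true concentration with log-normal noise
(multiplicative noise is how LC-MS response error behaves); decoy features
at uniform random m/z; application/detection histories constructed so that
parents of spiked TPs show use at the spike site. Retention times for
features and calibrants come from the same descriptor→RT line plus Gaussian
jitter, so the RT gate is exercised honestly.

Default scenario sizes (12 + 4 parents, 2 metabolites each, 8 spiked TPs,
15 decoys per sample, CV 10 %, 60 % library coverage, 70 % of parents
applied per site) keep a full pipeline run around a second while leaving
every decision branch populated; the test suite runs its multi-seed
pipeline properties on a slightly smaller variant (6 + 2 parents, 4 spikes,
5 decoys).

The generator deliberately omits chromatographic drift, matrix suppression,
in-source fragmentation, adduct diversity beyond (de)protonation, and
correlated noise. Passing tests therefore demonstrate that the decision
logic and numerics are correct under the stated model — not that the
workflow's real-data cascade (hundreds of raw hits thinning through manual
review) is reproduced; that depends on vendor peak picking and analyst
judgment outside any desk-scale artifact. The published cascade arithmetic
itself (42 retained = 23 + 19 rescued, 38 unique, 11 of 26 confirmed) *is*
checked, via `paper_shape_fixture()`, which encodes the evidence-tier and
polarity composition as a structural test of the decision rules.

## Numerical and degenerate-input choices

- Formulas round-trip through Hill notation; unknown elements and empty
  strings are parse errors naming the offending token.
- An empty MS2 spectrum scores tier weak with zero counts, never an error.
- A fragment heavier than its precursor has no subformula and counts as
  implausible; a candidate set is empty rather than an error when the target
  exceeds the precursor mass plus tolerance.
- An absent A+2 peak is a ratio of 0 (chlorine count 0).
- Calibration with fewer than two detected points is returned with
  `linearity_ok = FALSE` rather than erroring, so the `detected` fallback
  applies uniformly.
- Feature rows violating invariants are collected into a reject report with
  reasons; readers never silently drop rows.
- Scenario generation pins the RNG kind (Mersenne-Twister/Inversion/
  Rejection), so a seed yields byte-identical files across platforms.

## Known limitations

Only singly charged (de)protonated species are supported; multiply charged
ions, adduct networks and fine isotope structure are out of scope. The
spectral-library matcher counts peak matches within tolerance — it is not a
similarity score, and is not meant to replace one. Semiquantification
inherits every caveat of 3-point matrix-matched calibration with surrogate
internal standards; the ordinal ranges are the honest resolution of that
design, and the package never reports point estimates except as an attribute
for auditing.
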