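Package: tpscreen
Title: Monitoring-Integrated Suspect Screening of Pesticide Transformation
    Products in Surface Water
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Suspect screening of pesticide transformation products (TPs) in
    LC-HRMS surface-water data, integrating national pesticide-monitoring
    knowledge into the identification workflow. Provides elemental-formula
    arithmetic (monoisotopic masses, adduct m/z, chlorine isotope-pattern
    simulation and counting, subformula enumeration), suspect-list assembly
    from a monitored-target registry and a key-metabolite table, exact-mass
    feature matching with peak-shape and retention-time plausibility gates,
    fragment-evidence scoring against a local spectral library, retention
    decisions that rescue weak chemical evidence when monitoring data show
    parent presence or use, Schymanski-style confidence-level assignment,
    reference-standard confirmation, cross-polarity deduplication, and
    range-binned matrix-matched semiquantification. A seeded synthetic-scenario
    generator emulates the two-site, two-campaign study design with known
    ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
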