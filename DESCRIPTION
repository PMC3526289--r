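Package: dimelt
Title: Two-State Homodimer Melting and pH-Titration Analysis for
    Nucleic-Acid Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Van't Hoff analysis of spectroscopic (CD/UV) melting curves
    under a two-state homodimerization equilibrium, as used to
    characterize dimeric quadruplex and i-motif structures. Converts
    raw melting curves into the molar fraction of structured strands
    via linear folded/unfolded baselines, extracts the equilibrium
    constant at each temperature, fits lnK against 1/T to obtain the
    enthalpy and entropy of association with full error propagation,
    and analyses the concentration dependence of the melting
    temperature expected for multimolecular transitions. Also fits
    pH-titration curves to a Hill sigmoid to report the apparent pKa
    of an acid-stabilized structure, and generates synthetic melting
    and titration data with the same statistical structure for
    validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
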