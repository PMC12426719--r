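Package: hypnodense
Title: Hypnodensity-Based Analysis of Sleep Structure
Version: 0.1.0
Authors@R:
    person("Maarten", "Verhoeven", email = "m.verhoeven@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising sleep structure from automated
    sleep-stage classifiers that output per-epoch stage probability
    distributions (hypnodensities). Implements per-epoch ambiguity
    (normalised Shannon entropy), transition continuity (one minus the
    total-variation distance between the probability vectors flanking a
    stage transition), hypnogram bout/transition analysis, epoch-level
    agreement statistics (Cohen's kappa, per-class F1), and a
    group-comparison layer (Mann-Whitney U with rank-biserial effect
    sizes, Welch t-tests, Friedman tests, Benjamini-Hochberg FDR
    adjustment). Ships a synthetic cohort generator with Markov stage
    dynamics and Dirichlet hypnodensities so the full pipeline is
    testable without access-restricted polysomnography data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
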