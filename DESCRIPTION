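Package: statephys
Title: State-Dependent Electrophysiology and Behavioral Phenotyping for
    Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed wheel-running experiments in
    mouse models of Rett-syndrome-like interneuron dysfunction: locomotion
    state segmentation of wheel-sensor traces by change-point detection,
    state-conditioned local field potential (LFP) power spectra and relative
    band power, spike-field coherence, single-unit sorting-quality metrics
    (isolation distance, inter-spike-interval contamination) and
    locomotion-onset firing-rate modulation, scoring of four behavioral
    assays (elevated plus maze, open field, marble burying, three-chamber
    sociability), survival and seizure tabulation, and nonparametric group
    comparison (Kruskal-Wallis with Dunn's post-test). Ships a synthetic
    session and cohort generator with known ground truth so every stage is
    testable end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
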