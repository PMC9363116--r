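Package: pupdyn
Title: Population Dynamics and the Developmental Inhibition Switch in
    Neonatal Hippocampal Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of large-scale calcium imaging of the developing
    hippocampal CA1 network: detection of synchronous calcium events with
    circular-shift surrogates, peri-movement time histograms with
    permutation chance bands, post-movement activity and the
    inhibiting-movement classification that reveals the switch from
    movement-driven activation to movement-driven inhibition around
    postnatal day 9, movement- and immobility-associated cell detection,
    immobility-restricted population cross-correlograms, a two-population
    excitatory/inhibitory network model (rate equations with analytic
    noise-correlation predictions, and a sparse leaky integrate-and-fire
    network) in which strengthening somatic inhibition reproduces the
    switch, EMG vigilance-state scoring with twitch detection, early
    sharp-wave detection in layered LFP, synaptotagmin-2 bouton coverage
    quantification, and skeleton-based axon segmentation with activity
    clustering. Seeded synthetic-data generators emulate every input so
    the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
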