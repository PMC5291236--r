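Package: barreldev
Title: Quantitative Analysis of Thalamocortical Synapse and Barrel Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing minimal-stimulation thalamocortical EPSC
    recordings and barrel-cortex histology: success/failure detection and
    amplitude measurement on stimulus-locked current sweeps,
    single-exponential decay fitting, NMDA:AMPA ratios and ifenprodil
    inhibition, a binomial coincidence classifier for shared presynaptic
    axon inference from paired recordings, Barnard's unconditional exact
    test for 2x2 connectivity tables, barrel wall/hollow segregation
    scoring from nuclei point fields, axon crossing counts in rectangular
    regions of interest, and group-comparison statistics operating on raw
    per-animal values or printed (mean, SEM, N) summaries. Includes
    synthetic-data generators that emulate the statistical structure of
    the recordings and histology so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
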