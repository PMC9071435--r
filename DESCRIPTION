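Package: ligfid
Title: Ligation Fidelity and Sequence-Bias Profiling for DNA Ligase End-Joining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for profiling the fidelity and sequence bias of DNA ligases in
    cohesive end-joining, built around multiplexed four-base-overhang ligation
    assays. Provides a parametric generative model of competitive sticky-end
    ligation (per-overhang weights, a GC annealing coefficient, and per-type,
    per-position mismatch tolerances) with exact closed-form expectations and a
    multinomial simulator; extraction of overhang pairs from ligation-product
    strand reads with dual-orientation tabulation into a 256x256 pair-count
    matrix; the full set of reported statistics (normalized ligation frequency,
    overall and per-overhang fidelity, GC-stratified summaries, positional
    mismatch spectra, multi-mismatch distributions, pattern-group summaries,
    cross-sample Pearson correlations, and synthesis-bias correction from a
    randomized control region); and initial-velocity estimation for defined
    oligonucleotide ligation timecourses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
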