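Package: segclock
Title: Delay-Differential Models and Data Analysis for the Zebrafish Segmentation Clock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the core pacemaker circuit of the zebrafish segmentation
    clock: a delay differential equation model of the Her1, Her7, and Hes6
    transcriptional repressors in which all pairwise dimers form, but only
    Her1 homodimers and Her7:Hes6 heterodimers repress transcription.
    Provides a fixed-step method-of-steps integrator for systems with
    constant discrete delays, the reduced three-variable clock model and the
    full nine-variable mass-action dimer model, oscillation analysis (period,
    amplitude, damping classification), scripted in-silico experiments
    (production-rate sweeps, mutant panels, delay scans, sensitivity
    analysis), and the companion data-analysis procedures: relative-affinity
    estimation from microfluidic binding titrations, H-box motif scanning of
    promoter sequence, and somitogenesis-period estimation from
    somite-boundary timing with genotype comparisons. Seeded synthetic-data
    generators emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
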