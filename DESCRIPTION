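Package: lassocapture
Title: Coarse-Grained Simulation of LASSO Probe Capture Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts how the adapter length of long-adapter single-stranded
    oligonucleotide (LASSO) capture probes affects probe-target interaction
    free energy. Implements a reduced one-bead-per-nucleotide DNA model,
    Metropolis and Virtual Move Monte Carlo samplers, two-dimensional
    umbrella sampling over arm-target distance order parameters with
    adaptive flat-histogram weights, histogram unbiasing and interaction
    free-energy estimation, plus the sequencing-side enrichment statistics
    (RPKM, median-ratio enrichment, relative free energies, Pearson
    correlation) used to compare simulation with capture experiments.
    Includes a synthetic-data generator for probe/target systems and
    overdispersed read-count tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
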