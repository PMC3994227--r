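Package: snpga
Title: Genetic Algorithm Search for High-Risk Multi-SNP Genotype Models
    in Case-Control Data
Version: 0.1.0
Authors@R:
    person("snpga", "developers", email = "snpga@example.org", role = c("aut", "cre"))
Description: Detects multi-SNP genotype combination models associated with
    disease in case-control genotype data. A chromosome encodes a model as a
    set of (SNP, genotype) pairs; fitness is the difference between the model
    carrier frequency in cases and in controls, with repeated-SNP models
    penalized to zero. Provides a steady-state elitist genetic algorithm with
    rank-based parent selection, uniform crossover and one-point mutation, an
    exhaustive enumeration oracle for small model spaces, odds-ratio
    association statistics (Woolf confidence intervals, two-sided Wald
    p-values, add-one continuity correction for zero cells), a synthetic
    Hardy-Weinberg cohort generator with embeddable risk models, and a
    command-line pipeline producing per-order model tables and association
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
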