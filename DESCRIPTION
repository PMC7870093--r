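Package: neighbordist
Title: Distance Distribution Asymptotics for Nearest-Neighbor Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic asymptotic moments of pairwise distance distributions for
    the data types common in nearest-neighbor feature selection: standard and
    range-normalized L_q metrics on continuous data, genotype mismatch, allele
    mismatch and transition/transversion metrics for GWAS genotypes, and a
    region-of-interest metric for stacked time-series correlation data such as
    resting-state fMRI connectivity. Includes the extreme-value machinery behind
    max-min (range) normalization, seeded synthetic-data generators for every
    data model the theory assumes (including correlated variants built from
    random-graph correlation targets), a theory-versus-simulation validation
    harness, and distance-distribution-informed neighborhood sizing for
    Relief-style algorithms (MultiSURF radii, informed k).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
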