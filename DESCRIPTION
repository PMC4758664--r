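Package: bepith
Title: Branching Tumor Evolution Simulation and Multiregional
    Intratumor Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates tumor growth as a branching evolutionary process on a
    two-dimensional lattice (cellular automaton with driver-gene selection),
    performs in-silico multiregional sequencing of the simulated tumors, and
    fits the model to observed multiregional data by approximate Bayesian
    computation on founder/unique mutation summary statistics.  Also provides
    the matching analysis operators for real multiregional profiles of
    colorectal and other solid tumors: founder/shared/unique classification of
    somatic mutations, parsimony sample trees and their branch bipartitions,
    cancer-cell-fraction posteriors from read counts, purity and
    allele-specific copy number, founder/progressor copy-number calls from
    segmented log R ratios, founder/progressor methylation calls with
    permutation-based FDR control, methylation variance decomposition, clone
    color coding, and mutation-spectrum tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
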