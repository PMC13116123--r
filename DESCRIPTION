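Package: proxscreen
Title: Network-Proximity Screening of Compound Target Sets Against Disease
    Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico systems-pharmacology screening toolkit. Harmonizes
    compound-protein bioactivity records under four inclusion criteria and
    deduplicates compounds by InChIKey; computes the closest-distance network
    proximity between a compound's protein targets and a disease module on a
    protein-protein interaction network, with a degree-preserving permutation
    null, z-scores and p-values; clusters compounds from binary structural
    fingerprints; and provides the closed-form companion metrics used in a
    typical screening campaign (kinome percent-of-control and S(35)
    selectivity, Seahorse-style respirometry indices, behavioral indices,
    non-compartmental pharmacokinetics, an assay-precision statistic, and an
    annual fruit-and-vegetable-consumption cohort metric). Every pipeline
    input can be simulated with known ground truth, so the whole screen runs
    and is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
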