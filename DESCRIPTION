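Package: nitronet
Title: Weighted Co-Expression Networks and Metabolite Response Patterns for
    Nitrogen Treatments
Version: 0.1.0
Authors@R: person("Nitronet", "Maintainers", email = "maintainers@nitronet.dev",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks (soft-thresholded
    Pearson adjacency, topological overlap, dynamic tree cut, eigengene
    merging), associates module eigengenes with binary nitrogen
    condition/tissue traits, tests whether the top-ranked transcription
    factor in a module sits higher than chance by a permutation rank test,
    performs flat-annotation term enrichment (hypergeometric with
    Benjamini-Hochberg control), and classifies metabolite response
    patterns across nitrogen contrasts with Welch tests on log-transformed
    abundances. Ships a synthetic-data generator with planted modules,
    trait signals, hub transcription factors and metabolite effects so
    every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
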