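Package: modfinger
Title: Module Fingerprints for Blood Transcriptome Disease-Activity Analysis
Version: 0.1.0
Authors@R: person("SPARE", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential-expression and module-fingerprint analysis of
    normalized log2 expression matrices, as used to profile disease activity
    in systemic lupus erythematosus blood transcriptomes. Provides two-group
    empirical-Bayes moderated t-tests with Benjamini-Hochberg adjustment,
    directional per-module significance fingerprints, minimal-signature
    search by nearest shrunken centroids with cross-validated threshold
    selection, hierarchical clustering with activity-group separation
    scores, hypergeometric gene-set over-representation, and a seeded
    generator of module-structured synthetic cohorts so the whole pipeline
    is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
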