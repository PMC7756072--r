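Package: regenecomp
Title: Comparative Transcriptomics of Heart Regeneration and Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing injury time-course
    transcriptomes against paired tumor-normal cohorts: negative-binomial
    count simulation with planted ground truth, TMM normalization and
    count-matrix hygiene, moderated paired differential expression, a
    time-dependent modeled control with exponentially decaying sham
    influence, fuzzy c-means soft clustering of log2 fold-change
    trajectories, Fisher over-representation and paired gene-set
    statistics, gene-sharing term networks, ortholog-mapped
    cross-condition concordance, and a miRNA-mRNA anticorrelation screen
    with hypergeometric regulator merging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    igraph,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071,
    optparse
Config/testthat/edition: 3
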