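Package: gtomnet
Title: Gene Coexpression Network Analysis with GTOM and RECODE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of transcription-factor coexpression
    networks for two-group tumor cohorts. Implements eigenvalue-shrinkage
    denoising of high-dimensional expression matrices (RECODE), thresholded
    correlation networks, the generalized topological overlap measure GTOM(k),
    Ward-linkage module detection with a composite core/bridge total score for
    parameter selection, per-module patient Spearman-correlation networks with
    group-separation scoring, cluster annotation tables, and a planted-module
    synthetic expression generator providing ground truth for all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    withr
Config/testthat/edition: 3
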