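Package: pumar
Title: miRNA Regulatory Network Inference by Message Passing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers genome-wide bipartite miRNA-target gene regulatory
    networks by message passing (the PUMA algorithm, a miRNA-aware variant
    of the PANDA framework): a sequence-based target-prediction prior is
    iteratively refined against target-gene co-expression, while miRNA
    cooperativity is held fixed at its prior value.  Includes downstream
    analyses of network collections: tissue-specific edge and expression
    scores in median/IQR units, pre-ranked gene set enrichment on
    tissue-specific targeting profiles with permutation FDR, binarisation
    of signed enrichment scores and fast-greedy community detection on the
    resulting bipartite association graph, plus a synthetic-data generator
    with planted co-expression modules for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
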