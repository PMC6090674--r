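Package: cernaforge
Title: Competing Endogenous RNA Network Inference for Time-Series Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) networks from ordered
    time-series expression of mRNAs, lncRNAs, circRNAs and miRNAs, following
    the two-criterion procedure used in plant leaf-development studies: a
    hypergeometric test on shared miRNA regulators followed by a Pearson
    co-expression filter. Includes FPKM/RPM normalization with reproducibility
    and abundance filters, multi-caller back-splice junction merging and
    genomic classification of circRNAs, lncRNA candidate filtering by length
    and ORF content, union merging of miRNA-target predictions, global and
    stage-specific network assembly, hub identification and comparison,
    permutation and hypergeometric gene-set enrichment, temporal k-means
    clustering, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
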