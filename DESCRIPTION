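Package: promdiv
Title: Promoter-Architecture Divergence and Duplicate-Gene Retention Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing regulatory neo-functionalization of duplicated
    genes from promoter architectures and expression profiles. Builds
    fixed-width promoter windows around CAGE-defined transcription start
    sites, intersects them with ChIP-seq peak calls to obtain per-promoter
    transcription-factor binding architectures with a strong/weak quality
    split, and compares architectures with Manhattan distances, Jaccard
    indices and an independence-model architecture probability (expected
    versus observed frequency of a binary binding pattern). Includes a
    sampled-randomization co-expression test for TSS expression profiles,
    endothelial-style group enrichment and rank-sum z-score statistics,
    Monte-Carlo simulators of binding-site loss after gene duplication under
    the duplication-degeneration-complementation model (independent-site and
    clustered-site variants), synteny conservation assessment of two-gene
    clusters via one-to-one orthologs, likelihood-ratio-test arithmetic for
    nested codon models, and a synthetic-data generator with controllable
    ground truth so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    S4Vectors,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
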