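Package: modra
Title: Multi-Omics Drug Response Prediction with Latent Alignment and
    Co-Attention Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug response (log IC50) of cell lines from four
    omics views (mutation, copy number, methylation, expression). Each
    view is embedded by a two-layer feed-forward extractor, the four
    latent spaces are aligned with a contrastive loss that matches
    cross-view sample-similarity matrices to a soft target built from
    intra-view similarities, views are fused by bilinear co-attention,
    and a multi-drug regression head predicts responses. Includes
    DepMap-layout preprocessing (missingness filtering, all-zero gene
    removal, mean imputation, sample alignment), a synthetic multi-omics
    generator with shared latent structure, threefold cross-validation
    with median-threshold F1/AUROC, omics-masking importance, per-gene
    attribution, and hypergeometric gene-set enrichment.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
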