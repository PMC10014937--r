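Package: brainscape
Title: Batch-Corrected Reference Expression Landscapes of Normal and
    Neoplastic Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes bulk RNA-seq cohorts (FPKM/TPM) into a single
    batch-corrected log2(TPM) matrix, embeds the pooled samples into a
    2-D/3-D UMAP reference landscape, classifies adult diffuse gliomas
    into WHO-CNS5 molecular subtypes from IDH/1p19q marker calls,
    annotates the landscape with nearest-neighbor Kaplan-Meier median
    survival, scores pathways per sample with a single-sample gene-set
    variation statistic and moderated-t differential testing, and
    summarizes multi-omic overlays (mutation burden, gene-fusion counts,
    GISTIC-thresholded copy-number gains and losses). Ships a
    multi-cohort synthetic-data generator with known ground truth so
    every stage is testable without controlled-access downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    sva,
    uwot,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    digest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
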