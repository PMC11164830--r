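Package: spotgene
Title: Multi-Task Prediction of Spot-Level Gene Expression and Tumor
    Annotation from H&E Histology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts spatial-transcriptomics spot-level gene expression and
    binary pathological (tumor/normal) annotations from H&E-stained image
    patches with a multi-task convolutional model: a shared encoder feeds a
    primary regression head for the most highly expressed (target) genes, an
    auxiliary regression head for the remaining genes, and a tumor
    classification head, with a spatial-aware penalty that couples predicted
    expression of grid-adjacent spots sharing a pathological annotation.
    Includes spot/gene quality control and normalization for spatial
    transcriptomics counts, geometric patch extraction from whole-slide
    images, patient-level train/validation/test splits, per-gene evaluation
    metrics (aMSE, aPCC, NGPC, ACC, AUC, AUPRC), an ablation runner over the
    loss components, a differential-gene ranking, and a synthetic paired
    histology/expression simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    pROC,
    optparse,
    stats,
    utils,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
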