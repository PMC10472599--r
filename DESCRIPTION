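Package: leukotrace
Title: Tracing Chemoresistant Leukemic Cells in Paired Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying chemoresistant leukemic cells in
    paired pre-/post-chemotherapy single-cell RNA-seq samples: anchored
    co-clustering against a healthy haematopoietic reference with a
    cluster-composition malignancy rule, nearest-centroid cosine cell-type
    projection with "-like" labelling, single-cell genotype validation from
    barcoded read evidence (SNV alleles, fusion-junction soft clips and split
    UMIs, chromosome-Y loss, LAIP marker co-expression), chemoresistance
    signature scoring (module scores, the 17-gene leukemia stem cell score,
    permutation GSEA), signature-matrix construction with constrained
    weighted least-squares deconvolution of bulk cohorts, and patient-level
    statistics (Fisher exact, Kaplan-Meier/log-rank, Cox models, CD69-positive
    HSC-like stratification). A synthetic-data module generates all inputs
    with ground truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    survival,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
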