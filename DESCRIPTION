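Package: vcfusion
Title: Vertebral Morphometry and Decision-Level Fusion for Chronic Compression Fracture Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for chronic vertebral compression fracture (VCF) decision
    pipelines on sagittal vertebral-body masks: Genant height-loss-ratio (HLR)
    morphometry from label masks, vertebral contour-band extraction by
    morphological dilation, YOLO-style detector output parsing and box-to-vertebra
    matching, four decision-level fusion strategies combining HLR with detector
    confidence, and a full evaluation suite (pixel-overlap metrics, vertebra-wise
    classification metrics with exact binomial confidence intervals, ROC and
    AUROC). A synthetic spine-phantom generator with controlled anterior, middle
    and posterior heights and deformity classes, plus a calibrated mock detector,
    make the whole pipeline testable end to end without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
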