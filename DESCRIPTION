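Package: SinusDx
Title: Rule-Based Clinical Decision Support for Sinusitis Assessment from
    Nasal-Endoscopy Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a rule-based clinical decision algorithm that turns
    multi-class nasal-endoscopy instance detections (middle turbinate,
    inferior turbinate, mucus) into a binary sinusitis call. The middle
    meatus, often not directly visible endoscopically, is localized
    geometrically from turbinate segmentation masks with a primary
    (both-turbinate) and a fallback (middle-turbinate-only) construction;
    a positive diagnosis is triggered when the bounding-box intersection
    over union between detected mucus and the inferred middle-meatus
    region (or, by the fallback pathway, the middle turbinate) exceeds a
    threshold. The package reads COCO-style and YOLO-segmentation
    annotations, provides the complete evaluation stack (per-class
    segmentation metrics, laterality-stratified classification metrics,
    ROC/AUC with bootstrap confidence intervals, trigger-pathway
    accounting, inter-rater agreement) and a seeded generator of
    synthetic annotation scenes with construction-time ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
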