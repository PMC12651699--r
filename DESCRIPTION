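Package: dentalign
Title: FDI Tooth-Numbering Post-Processing for Dental Radiograph Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and evaluation toolkit for FDI tooth-numbering
    object detectors on periapical radiographs. Provides the FDI two-digit
    code system and its linear arch index, spatial soft labels over the 32
    permanent teeth with a Kullback-Leibler divergence loss, a
    sliding-template sequence-correction algorithm that repairs mislabelled
    detections and inserts placeholders for missing teeth, a full detection
    evaluation suite (precision, sensitivity, specificity, F1, mAP50,
    FDI position error, top-1 confidence, per-class confusion), a synthetic
    detection-scenario generator for benchmarking without radiographs, and
    readers/writers for LabelImg-style Pascal VOC XML annotations and a
    COCO-flavoured detection JSON dialect, with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
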