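Package: cinresist
Title: Copy-Number Signature Biomarkers of Chemotherapy Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for chromosomal-instability (CIN)
    signature biomarkers of chemotherapy resistance. Covers binned
    shallow whole-genome copy-number profiling (GC/mappability
    correction, penalized changepoint segmentation), relative-to-absolute
    copy-number transformation with purity/ploidy grid-search fitting,
    off-target copy-number calling from capture-panel reads, copy-number
    feature extraction and sum-of-posterior encoding, non-negative
    linear decomposition onto a fixed signature matrix, rule-based
    platinum/taxane/anthracycline resistance classifiers, and emulated
    phase 2/3 biomarker trials from clinical treatment-line tables with
    inverse probability weighting and proportional-hazards estimation.
    Ships synthetic-data generators with known ground truth for every
    pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
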