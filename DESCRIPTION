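Package: crscreen
Title: Chemical-Genomics Screening Analysis of Super-Enhancer-Driven Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-reporter chemical screens that probe
    super-enhancer (SE)-driven versus promoter-driven transcription, together
    with the regulatory-genomics stages used to interpret the hits. Provides
    plate normalization to negative controls and Z-factor assay QC, the
    weighted (4L + 2C + X)/7 hit score, four-parameter logistic dose-response
    fitting with SE-selectivity classification, time-resolved growth IC50
    trajectories, fluorogenic deacetylase progress-curve isoform panels, and
    SE-centric interval analysis (peak filtering, 12.5 kb stitching,
    hockey-stick SE calling, occupancy, co-binding, ranked-list enrichment).
    A synthetic-data module generates every input with planted ground truth so
    the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
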