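Package: cmquant
Title: Quantification of Cardiomyocyte Maturation Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification procedures for assessing cardiomyocyte maturation
    from imaging and functional assays: sarcomere alignment index from
    structure-tensor orientation histograms, sarcomere length from line-scan
    intensity profiles (spectral and peak-spacing estimators), percent
    sarcomere shortening from paced contraction time-lapses, calcium-transient
    kinetics (time to peak, peak amplitude, decay time) from delta-F/F0
    traces, mitochondrial stress-test oxygen consumption rate partitioning
    (basal, ATP-linked, proton leak, maximal), per-cell morphometry and
    binucleation from label masks, and control-quantile fluorescence gating.
    Seeded synthetic-data generators emulate every input modality with known
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
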