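Package: replireset
Title: Simulation and Analysis Toolkit for Replication-Reset Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for studying replication reset in fast-growing
    bacteria: CRISPRi synthetic-essentiality screen analysis (guide counting,
    negative-binomial count modelling, leave-one-out regression interaction
    calling), Luria-Delbruck fluctuation analysis (Ma-Sandri-Sarkar maximum
    likelihood mutation-rate estimation and one-sided rate comparison),
    flow-cytometry DNA-content quantification (density peak detection, DAPI to
    chromosome-number calibration, chromosome-fraction summaries), and
    circular-genome coverage analytics for replication run-out and strand-
    oriented DNA-end sequencing (binning, CPM and terminus normalization,
    smoothing and outlier trimming, replicore asymmetry, degradation-plateau
    detection, orientation statistics). Includes seeded synthetic-data
    generators with known ground truth for every input class, emulating
    multifork replication, fork stalling and rear-ending, replicore
    degradation, and one-ended DNA-end tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
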