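Package: rrbsdml
Title: Differential Methylation Calling and Regulatory Integration for
    Replicated Bisulfite Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls differentially methylated loci (DML) between two groups
    of replicated reduced-representation bisulfite sequencing (RRBS)
    samples with a beta-binomial Wald test and empirical-Bayes dispersion
    shrinkage, applies group-level coverage filtering and spike-in based
    conversion-efficiency QC, annotates DML to the nearest transcription
    start site, integrates them with differential expression, quantifies
    DML proximity to accessible-chromatin peaks with a shuffle-based
    permutation null, and tests position-weight-matrix motif enrichment
    around demethylated loci. A fully seeded synthetic-data generator
    produces methylomes with spiked differentially methylated regions,
    spike-in conversion controls, peak sets, signal tracks, expression
    tables and planted motifs, so the whole pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
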