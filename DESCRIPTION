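Package: occudiff
Title: Spike-In Normalized Differential Occupancy Analysis for ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential chromatin occupancy analysis for spike-in calibrated
    ChIP-seq of transcription machinery (elongation factors, total and
    Ser2-phosphorylated RNA polymerase II) across matched mutant/wild-type
    animal pairs. Provides exogenous spike-in scale-factor normalization,
    occupied-gene universe filtering (polymerase occupancy, gene length,
    neighbour distance), scale-regions occupancy matrices around TSS, gene
    body and TES, per-pair log2 fold-change matrices, hierarchical clustering
    of occupancy-change profiles, matched-pair median-of-ratios gene
    summaries, cluster-wise Spearman correlation of factor versus polymerase
    occupancy changes and RNA expression, and a deterministic synthetic-data
    generator with planted cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
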