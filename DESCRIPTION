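Package: caldep
Title: Calcium-Dependency Classification of Hydrogen Peroxide Responsive
    Genes with Regulatory Path Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the crosstalk between cytosolic calcium
    signalling and hydrogen peroxide (H2O2) induced transcriptional
    reprogramming from paired differential-expression contrasts (H2O2,
    H2O2 plus the calcium-channel blocker LaCl3, and LaCl3 alone).
    Implements a delta-log2-fold-change dependency classifier that
    assigns each H2O2-responsive gene a calcium-dependency class (strict,
    partial/additive, enhanced, antagonistic, independent), k-means
    clustering of response profiles with gap-statistic selection of the
    number of clusters, constrained regulatory-path extraction from
    calcium-signalling source genes to target genes through a ranked,
    typed molecular-interaction knowledge network (maximum path length
    three, a single terminal transcription-regulation edge, closest-source
    reduction, merging and hub scoring), ortholog mapping by best BLAST
    hit, 2^-ddCt qPCR quantification against dual reference genes, and
    baseline-subtracted peak extraction for calcium reporter traces.
    A seeded synthetic-data module generates negative-binomial counts,
    differential-expression tables, knowledge networks and Ct tables with
    planted ground truth for recovery-based validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
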