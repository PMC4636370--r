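Package: omicsnr
Title: Signal-to-Noise Based Differential Expression for Paired
    Transcriptome-Proteome Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a score-based differential-expression pipeline for
    two-state, two-replicate multi-omics designs: exact 100-mer read counting
    against gene models, total-ion-count (TIC) rollup of peptide evidence to
    protein abundances with identification filters, cross-state (Z) versus
    intra-replicate (R) scoring with a rank-based inverse-normal transform and
    the +/-1.65 outermost-10 percent call rule, system and per-feature
    signal-to-noise ratios with Monte-Carlo false-discovery-rate calibration,
    RNA-protein correlation quality control, COG category summaries, and the
    qPCR standard-curve and summary-statistics t-test used for validation.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
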