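Package: mlpaGCR
Title: MLPA-Based Analysis of Gross Chromosomal Rearrangements in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing gross chromosomal rearrangements (GCRs) in
    Saccharomyces cerevisiae-like genomes with multiplex ligation-dependent
    probe amplification (MLPA). Models the genomic landscape of Ty1/Ty2
    retrotransposons and solo delta elements, designs telomeric, centromeric
    and arm-specific probe panels, converts capillary peak-area tables into
    integer copy-number calls, classifies arm deletions/duplications and
    whole-chromosome duplications, localizes translocation breakpoints to
    candidate Ty recombination targets, and provides fluctuation-assay rate
    estimation with nonparametric median confidence intervals, per-arm
    observed-versus-expected duplication rates, and Monte Carlo multinomial
    and exact tests for translocation hotspot detection. A synthetic-data
    module generates annotations, event cohorts, noisy peak tables and
    fluctuation cultures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
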