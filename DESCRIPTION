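Package: apadyn
Title: Dynamic Alternative Polyadenylation Analysis for 3'-Tag Single-Cell Data
Version: 0.1.0
Authors@R:
    person("APA", "Maintainers", email = "maintainers@apadyn.dev", role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) from 3'-tag single-cell
    RNA-seq alignments. Calls polyadenylation-site (PAS) peaks inside annotated
    3'UTRs and introns, removes internal-priming artifacts with A-run and CPM
    filters, computes proximal (pPUI) and intronic (iPUI) PAS usage indices at
    cluster and single-cell level, tests differential PAS usage with chi-squared
    tests under Benjamini-Hochberg FDR control, calls cell-type- and
    stage-specific APA events with an entropy-based ROKU procedure, scans
    canonical poly(A) signals around peak 3' edges, benchmarks peaks against
    known PAS catalogues, and evaluates qPCR-based relative expression of
    proximal-PAS transcripts. Ships a seeded simulator of 3'-tag data with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
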