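Package: ldipcr
Title: Detection and Characterization of Somatic L1 3' Transductions from
    Long-Distance Inverse PCR Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls and characterizes somatic LINE-1 (L1) 3'-transduction
    insertions from long-read sequencing of long-distance inverse-PCR
    (LDI-PCR) amplicons. Implements hallmark chimeric-read detection,
    breakpoint extraction and clustering with a filter cascade (read
    support, restriction cut-site distance, contig whitelist, barcode
    crosstalk majority), partial-order-alignment consensus polishing of
    amplicon reads, and full insertion characterization (target-site
    duplication or deletion, twin-priming inversion point, junction
    microhomology, polyA tail and terminating polyadenylation signal,
    orphan-transduction status, insertion length). Includes an in-silico
    model of restriction digestion, self-circularization and inverse-PCR
    amplicon prediction, and a seeded simulator producing genomes, planted
    transductions, noisy Nanopore-like reads and alignment records so every
    stage is testable without external data, plus summary statistics
    (Wilcoxon rank-sum with continuity correction) over insertion
    catalogues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
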