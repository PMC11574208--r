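Package: tertuv
Title: Two-Step UV Mutagenesis Analysis of the TERT Promoter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the two-step origin of atypical TERT promoter
    mutations: a promoter coordinate and ETS-motif model with prediction of UV
    damage (CPD) hotspot bases at occupied binding sites; cohort-level
    co-occurrence and UV-burden statistics on MAF-style somatic mutation
    tables; mutational-spectrum construction with forward-selection
    non-negative signature fitting and dipyrimidine C>T burden; read-backed
    cis/trans phasing of closely spaced promoter variants from SAM alignments;
    a simplified UMI-consensus caller for ultrasensitive amplicon sequencing
    with driver-phased subclonal mutation detection; and a genome-wide paired
    ETS-site spacing and ChIP-peak co-occupancy scan. Seeded synthetic-data
    generators emulate every input class so the whole pipeline is testable
    without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
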