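Package: minied
Title: RNA Editing Analysis for Dinoflagellate Plastid Minicircle Genes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and consequence analysis of RNA editing in
    dinoflagellate plastid minicircle genes. Calls RNA-DNA differences from
    mapped RNA-seq and DNA-seq read pileups with coverage, SNP-exclusion and
    strand/position-bias filters; classifies the twelve possible editing
    types; annotates codon-level consequences including stop-codon
    restoration; summarises editing per gene and in aggregate (type spectrum,
    codon-position distribution, GC shift, homolog identity, molecular weight
    and GRAVY hydropathy shifts); scans minicircle core regions for GC-rich
    inverted repeats, the conserved CACCAATGCACC RNA-binding motif and
    transcription start sites; and ships a planted-truth read simulator so
    the whole pipeline is testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
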