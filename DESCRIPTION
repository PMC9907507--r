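Package: ctdprof
Title: Comparative Profiling of CtBP C-Terminal Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the intrinsically disordered
    C-terminal domain (CTD) of the CtBP transcriptional corepressor family.
    Provides anchor-motif domain segmentation of CtBP-like proteins into
    NTD, dehydrogenase core and CTD; global pairwise alignment with
    anchored-window percent identity; amino-acid composition profiling of
    disordered tails (P/G/A content, hydrophobicity, FCR/NCPR) with
    Das-Pappu phase classification; alignment-column conservation
    annotation and conserved-block extraction; rule-based vertebrate
    paralog calling with SUMO-consensus scanning and reference-site
    auditing; and a seeded generator of synthetic CtBP-like protein
    families with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
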