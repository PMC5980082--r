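Package: wrkyscan
Title: Identification, Classification and Expression Analysis of WRKY Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide identification and classification of
    WRKY transcription factors from protein sequences. Detects WRKY domains by
    their conserved heptapeptide (WRKYGQK and listed variants) followed by a
    C2H2 or C2HC zinc-finger pattern with bounded spacers, classifies proteins
    into Group I, IIa-IIe and III by structural rules plus reference-guided
    neighbor-joining placement with Poisson-corrected distances, annotates
    accessory regulatory motifs (EAR, LxxLL, HARF, leucine zipper), and
    analyses expression (log2 fold-change contrasts, hierarchical clustering,
    qPCR 2^-ddCt). A synthetic-data generator produces ground-truth-labelled
    proteins, reference panels, expression matrices and Ct tables so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
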