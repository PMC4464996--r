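Package: ssrmir
Title: Plant Pre-miRNA Prediction from Homology and SSR Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts plant precursor and mature microRNAs by combining
    homology scanning of EST/GSS sequences against known mature miRNAs with
    RNA-folding descriptors (AMFE, MFEI, normalized Shannon entropy,
    normalized base-pair distance, base-pairing propensity) screened against
    99 percent probability cutoff ranges, and conserved trinucleotide simple
    sequence repeat (SSR) family signatures. Includes a built-in minimum
    free energy folder with McCaskill-style ensemble base-pair
    probabilities, a seven-criterion candidate filter with best-window
    selection, confusion-matrix and small-RNA expression validation
    utilities (TPM, 2^-dCT), and seeded synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
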