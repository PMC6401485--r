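Package: cascr
Title: CRISPR Spacer Discovery, Validation, and Protospacer Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage discovery and validation of CRISPR repeat-spacer arrays
    in metagenomic reads and contigs, in the style of the CASC pipeline. A
    CRT-like exact-word scan proposes candidate arrays, which are then
    validated by Cas-protein homology, known-repeat homology, or spacer-length
    regularity, under liberal or conservative modes. Includes a self-contained
    seeded local-alignment search with Karlin-Altschul E-value statistics
    (nucleotide and translated modes), sequencing-effort-normalized spacer
    abundance, spacer-to-virome protospacer matching with ORF assignment and
    spanning detection, cumulative-bit-score functional annotation with
    actual/expected fold-change enrichment, and a synthetic-metagenome
    generator with planted-truth evaluation of sensitivity and precision.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    geosphere,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
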