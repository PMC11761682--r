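Package: vnarmine
Title: NGS-Guided Mining of Immunized VNAR Phage-Display Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for next-generation sequencing of immunized
    shark single-domain antibody (VNAR) phage-display libraries. Turns raw
    paired-end amplicon reads into ranked unique VNAR proteins (quality
    trimming, overlap merging, conserved-flank filtering, in-frame
    translation, stop-codon filtering), annotates framework and
    hypervariable regions, profiles cysteine architecture to classify
    subtypes I-IV, clusters CDR3 clonotypes by percent identity, and mines
    target-unique clades by differential comparison of an antigen-immunized
    library against a control-immunized library to nominate candidate
    binders without biopanning. Includes a seeded synthetic-repertoire
    generator with ground-truth manifests for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
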