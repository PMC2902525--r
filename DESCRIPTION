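Package: flcDNA
Title: Identification and Characterization of Full-Length cDNAs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying and characterizing full-length cDNA
    sequences from EST projects in closely related species pairs.
    Classifies transcripts by the conserved-start-codon rule against
    translated-search hits, annotates ORFs and UTRs, detects and trims
    poly(A) tails, calls polyadenylation signal hexamers in the 35-bp
    window upstream of the tail and discovers over-represented hexamers
    among non-canonical transcripts, profiles the Kozak start-codon
    context, scans UTRs with a simplified stem-loop motif descriptor
    engine, compares ortholog ORF and 3'UTR percent identities between
    two species, and discriminates paralogs from allelic variants with
    Poisson-corrected distances, neighbor joining and bootstrap support.
    A synthetic-data generator with full ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, Annotation, Phylogenetics
RoxygenNote: 7.3.3
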