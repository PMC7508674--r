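Package: viromescan
Title: Discovery and Characterization of RNA-Virus RdRPs in Aquatic Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational stages used to
    discover RNA-dependent RNA polymerases (RdRPs) in bulk aquatic
    metatranscriptomes: quality trimming and exact k-mer subtraction of
    DNA-library reads, unification of contig sets by shared 15-mer content,
    six-frame stop-to-stop translation with position-specific scoring matrix
    (PSSM) scanning of the RdRP core, assignment of alternative genetic codes
    by stop-codon census, detection and restoration of permuted RdRP motif
    order, greedy identity clustering, neighbor-joining trees with
    metagenome-clade delineation, CRISPR-spacer protospacer matching, and
    per-contig RPKM abundance summaries. Includes a ground-truthed synthetic
    virome generator so every stage is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
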