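Package: graphpolish
Title: Hybrid Error Correction of Noisy Long Reads with a Colored de Bruijn Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-pass hybrid error correction of noisy genomic long reads
    (Oxford Nanopore scale error profiles) using accurate paired short reads.
    Short reads are assembled into a compacted de Bruijn graph whose k-mers
    carry color sets (read-of-origin identifiers) and IUPAC annotations of
    candidate SNP sites. Long reads are anchored on the graph with exact and
    single-edit k-mer matches, and the non-anchored regions are corrected by a
    greedy color- and similarity-guided graph traversal, with a conservative
    haplotype-aware restoration of candidate SNP alleles. Includes a seeded
    diploid read simulator with full truth tracking, a truth-based evaluator,
    reference-guided read binning from SAM or PAF alignments, and GFA1 export
    of the graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    tibble,
    dplyr,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
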