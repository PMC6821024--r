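Package: dmnl
Title: Dimer-Mitogenome and Non-Random Loss Analysis of Mitochondrial Gene
    Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genomic-scale mitochondrial gene rearrangements
    under the Dimer-Mitogenome and Non-Random Loss (DMNL) model, with the
    bothid flatfishes as the motivating system.  Simulates DMNL variants from
    the ancestral teleost gene order (dimerization, promoter loss, non-random
    gene loss with the tRNA-Asn retention rule, gene degeneration), classifies
    observed gene orders into four rearrangement types, decides tRNA-Asp
    translocation timing by parsimony, traces intergenic spacers back to
    degenerated genes, detects light-strand replication-origin stem-loops and
    control-region motifs and tandem repeats, and generates annotated
    synthetic mitogenomes with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
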