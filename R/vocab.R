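# Controlled vocabulary for mitochondrial features.
#
# Protein and rRNA genes by conventional symbols; tRNAs by single-letter
# amino-acid code with S1 = tRNA-Ser(UCN), L1 = tRNA-Leu(UUR) and S2/L2 the
# other isoacceptors.  CR/CR1/CR2 are control regions, OL the light-strand
# replication origin, SPACER a degenerate intergenic remnant.

.protein_genes <- c("ND1", "ND2", "COI", "COII", "COIII", "ATP6", "ATP8",
                    "ND3", "ND4L", "ND4", "ND5", "ND6", "CytB")
.rrna_genes <- c("12S", "16S")
.trna_genes <- c("F", "V", "L1", "I", "Q", "M", "W", "A", "N", "C", "Y",
                 "S1", "D", "K", "G", "R", "H", "S2", "L2", "E", "T", "P")
.control_features <- c("CR", "CR1", "CR2")
.origin_features <- "OL"
.spacer_features <- "SPACER"

# Genes transcribed from the light strand in the ancestral vertebrate order.
.l_strand_genes <- c("Q", "A", "N", "C", "Y", "S1", "ND6", "E", "P")

#' Feature category for a controlled-vocabulary name
#'
#' @param name character vector of feature names (e.g. `"ND1"`, `"S1"`,
#'   `"CR2"`).
#' @return character vector with values `"protein"`, `"rRNA"`, `"tRNA"`,
#'   `"control"`, `"origin"` or `"spacer"`.
#' @examples
#' feature_category(c("12S", "D", "CR1", "OL"))
#' @export
feature_category <- function(name) {
  out <- rep(NA_character_, length(name))
  out[name %in% .protein_genes] <- "protein"
  out[name %in% .rrna_genes] <- "rRNA"
  out[name %in% .trna_genes] <- "tRNA"
  out[name %in% .control_features] <- "control"
  out[name %in% .origin_features] <- "origin"
  out[name %in% .spacer_features] <- "spacer"
  if (anyNA(out)) {
    stop("unknown feature name(s): ",
         paste(unique(name[is.na(out)]), collapse = ", "))
  }
  out
}

#' All controlled-vocabulary feature names
#'
#' @return character vector of every legal feature name.
#' @export
feature_vocabulary <- function() {
  c(.protein_genes, .rrna_genes, .trna_genes,
    .control_features, .origin_features, .spacer_features)
}

# categories counted as genes (37 in a canonical monomer)
.gene_categories <- c("protein", "rRNA", "tRNA")

is_gene_category <- function(category) category %in% .gene_categories
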