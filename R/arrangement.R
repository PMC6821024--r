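# Circular gene-order arrangements.
#
# A `mito_arrangement` holds an ordered, circular list of stranded features as
# a data frame.  Gene orders are pure sequences at this layer: base-level
# coordinates belong to annotated sequences (see synth_sequence).  The
# internal representation is rotation-canonicalized at tRNA-F (or at the
# lexicographically smallest feature if F is absent) so that serialization
# and equality are stable.

new_features <- function(name = character(), strand = character(),
                         category = NULL, copy = NULL,
                         provenance = NA_character_, length_bp = NA_integer_) {
  if (is.null(category)) category <- feature_category(name)
  if (is.null(copy)) copy <- rep("plain", length(name))
  data.frame(name = as.character(name),
             strand = as.character(strand),
             category = as.character(category),
             copy = rep_len(as.character(copy), length(name)),
             provenance = rep_len(as.character(provenance), length(name)),
             length_bp = rep_len(as.integer(length_bp), length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a circular mitochondrial gene arrangement
#'
#' @param features data frame with columns `name`, `strand` (`"H"`/`"L"`),
#'   and optionally `category`, `copy` (`"plain"`/`"prime"`), `provenance`
#'   (spacers only) and `length_bp`.
#' @param anchor feature name used to linearize the circle for display and
#'   serialization; defaults to tRNA-F when present.
#' @param is_dimer logical; `TRUE` for a head-to-tail dimer.
#' @param validate check invariants (vocabulary membership, duplicate genes).
#' @return an object of class `mito_arrangement`.
#' @details Control, origin and spacer features carry strand `"H"` by
#'   convention; strand counts ignore them.  Provenance may be set only on
#'   spacers.
#' @seealso [canonical_teleost_order()], [bothid_fixture()],
#'   [arrangements_equal()]
#' @export
arrangement <- function(features, anchor = "F", is_dimer = FALSE,
                        validate = TRUE) {
  stopifnot(is.data.frame(features))
  n <- nrow(features)
  if (is.null(features$category)) features$category <- feature_category(features$name)
  if (is.null(features$copy)) features$copy <- rep("plain", n)
  if (is.null(features$provenance)) features$provenance <- rep(NA_character_, n)
  if (is.null(features$length_bp)) features$length_bp <- rep(NA_integer_, n)
  features <- features[, c("name", "strand", "category", "copy",
                           "provenance", "length_bp")]
  rownames(features) <- NULL
  x <- structure(list(features = features, anchor = anchor,
                      is_dimer = is_dimer),
                 class = "mito_arrangement")
  x <- canonicalize_rotation(x)
  if (validate) validate_arrangement(x)
  x
}

validate_arrangement <- function(x) {
  f <- x$features
  ok_names <- f$name %in% feature_vocabulary()
  if (!all(ok_names)) {
    stop("unknown feature name(s): ",
         paste(unique(f$name[!ok_names]), collapse = ", "))
  }
  expected_cat <- feature_category(f$name)
  if (!identical(expected_cat, f$category)) {
    bad <- which(expected_cat != f$category)[1]
    stop("category '", f$category[bad], "' inconsistent with name '",
         f$name[bad], "'")
  }
  if (!all(f$strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'")
  if (any(!is.na(f$provenance) & f$category != "spacer")) {
    stop("provenance may be set only on spacer features")
  }
  genes <- f[is_gene_category(f$category), ]
  dup <- duplicated(genes[, c("name", "copy")])
  if (any(dup)) {
    stop("duplicate gene(s) in arrangement: ",
         paste(unique(genes$name[dup]), collapse = ", "))
  }
  if (!x$is_dimer && any(genes$copy != "plain")) {
    stop("monomer features must carry copy = 'plain'")
  }
  invisible(x)
}

# Rotate so that the anchor feature (or the lexicographically smallest name)
# comes first.  For dimers the plain-copy anchor is used.
canonicalize_rotation <- function(x) {
  f <- x$features
  if (nrow(f) == 0L) return(x)
  idx <- which(f$name == x$anchor & f$copy == "plain")
  if (length(idx) == 0L) idx <- which(f$name == x$anchor)
  if (length(idx) == 0L) idx <- which(f$name == min(f$name))
  i <- idx[1]
  if (i > 1L) {
    f <- f[c(i:nrow(f), 1:(i - 1L)), ]
    rownames(f) <- NULL
    x$features <- f
  }
  x
}

#' Rotate a circular arrangement
#'
#' Rotation does not change the arrangement as a circular object (equality is
#' rotation-invariant); this helper exists for testing and display.
#'
#' @param x a `mito_arrangement`.
#' @param k number of positions to rotate by.
#' @return a `mito_arrangement` whose stored linearization starts `k`
#'   features later (then re-canonicalized on construction of derived
#'   objects).
#' @export
rotate_arrangement <- function(x, k) {
  n <- nrow(x$features)
  if (n == 0L) return(x)
  idx <- ((seq_len(n) - 1L + as.integer(k)) %% n) + 1L
  f <- x$features[idx, , drop = FALSE]
  rownames(f) <- NULL
  x$features <- f
  x
}

#' The ancestral (canonical) teleost mitochondrial gene order
#'
#' Returns the typical vertebrate/teleost arrangement linearized at tRNA-F:
#' 37 genes (13 protein-coding, 2 rRNA, 22 tRNA) plus the control region and
#' the light-strand replication origin O_L between tRNA-N and tRNA-C.  ND6
#' and eight tRNAs (Q, A, N, C, Y, S1, E, P) lie on the L-strand; everything
#' else on the H-strand.
#'
#' @return a `mito_arrangement` (monomer, 39 features).
#' @examples
#' canonical_teleost_order()
#' strand_counts(canonical_teleost_order())
#' @export
canonical_teleost_order <- function() {
  nm <- c("F", "12S", "V", "16S", "L1", "ND1", "I", "Q", "M", "ND2", "W",
          "A", "N", "OL", "C", "Y", "COI", "S1", "D", "COII", "K", "ATP8",
          "ATP6", "COIII", "G", "ND3", "R", "ND4L", "ND4", "H", "S2", "L2",
          "ND5", "ND6", "E", "CytB", "T", "P", "CR")
  strand <- ifelse(nm %in% .l_strand_genes, "L", "H")
  arrangement(new_features(nm, strand))
}

# tail (from tRNA-T onwards, exclusive) per rearrangement type; the H-block
# F..T is shared by all 13 bothid gene orders.
.bothid_species <- list(
  "C.az" = "I", "C.ko" = "I", "C.va" = "I",
  "B.my" = "II", "A.po" = "II", "C.lu" = "II",
  "G.p" = "III", "A.t" = "III", "L.g" = "III", "L.l" = "III", "P.i" = "III",
  "B.pa" = "IV", "A.in" = "IV")

#' Species codes of the 13 bothid gene-order fixtures
#'
#' @return named character vector mapping species code to rearrangement type
#'   (I-IV).
#' @export
bothid_species_codes <- function() {
  vapply(.bothid_species, identity, character(1))
}

#' Observed gene order of a bothid mitogenome
#'
#' Encodes the 13 rearranged bothid gene orders.  All retain the H-strand
#' block F, 12S, (V,) 16S, L1, ND1, I, M, ND2, W, N(L), O_L, COI, COII, K,
#' ATP8, ATP6, COIII, G, ND3, R, ND4L, ND4, H, S2, L2, ND5, CytB, T, and an
#' L-strand gene cluster whose layout relative to the control region(s) and
#' tRNA-D defines the type:
#' \describe{
#'   \item{Type I (C.az, C.ko, C.va)}{... T, D, CR, Q-A-C-Y-S1-ND6-E-P}
#'   \item{Type II (B.my, A.po, C.lu)}{... T, CR, Q-A-C-Y-S1, D, ND6-E-P}
#'   \item{Type III (G.p, A.t, L.g, L.l, P.i)}{... T, CR1, Q-A-C-Y-S1, D,
#'     ND6-E-P, CR2}
#'   \item{Type IV (B.pa, A.in)}{... T, Q-A-C-Y-S1, D, ND6-E-P, CR; A.in
#'     additionally has tRNA-V shuffled from 12S-V-16S to 16S-V-L1}
#' }
#'
#' @param species_code one of `names(bothid_species_codes())`, e.g. `"G.p"`
#'   for *Grammatobothus polyophthalmus* or `"C.az"` for *Crossorhombus
#'   azureus*.
#' @return a `mito_arrangement` monomer with 37 genes.
#' @examples
#' bothid_fixture("G.p")
#' @export
bothid_fixture <- function(species_code) {
  if (!species_code %in% names(.bothid_species)) {
    stop("unknown species code '", species_code, "'; expected one of ",
         paste(names(.bothid_species), collapse = ", "))
  }
  type <- .bothid_species[[species_code]]
  head_block <- c("F", "12S", "V", "16S", "L1", "ND1", "I", "M", "ND2", "W",
                  "N", "OL", "COI", "COII", "K", "ATP8", "ATP6", "COIII",
                  "G", "ND3", "R", "ND4L", "ND4", "H", "S2", "L2", "ND5",
                  "CytB", "T")
  if (species_code == "A.in") {
    head_block <- c("F", "12S", "16S", "V", "L1", head_block[-(1:5)])
  }
  tail_block <- switch(type,
    "I"   = c("D", "CR", "Q", "A", "C", "Y", "S1", "ND6", "E", "P"),
    "II"  = c("CR", "Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P"),
    "III" = c("CR1", "Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P", "CR2"),
    "IV"  = c("Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P", "CR"))
  nm <- c(head_block, tail_block)
  strand <- ifelse(nm %in% .l_strand_genes, "L", "H")
  arrangement(new_features(nm, strand))
}

#' Count genes by strand
#'
#' Counts features of the gene categories (protein, rRNA, tRNA) on the heavy
#' and light strands; control regions, O_L and spacers are ignored.
#'
#' @param x a `mito_arrangement` monomer.
#' @return named integer vector `c(H = ..., L = ...)`.
#' @examples
#' strand_counts(bothid_fixture("G.p"))  # 28 H, 9 L
#' @export
strand_counts <- function(x) {
  stopifnot(inherits(x, "mito_arrangement"))
  g <- x$features[is_gene_category(x$features$category), ]
  c(H = sum(g$strand == "H"), L = sum(g$strand == "L"))
}

# name+strand (and optionally copy) token sequence used for equality
.equality_tokens <- function(x, include_spacers, use_copy) {
  f <- x$features
  if (!include_spacers) f <- f[f$category != "spacer", , drop = FALSE]
  # CR1/CR2/CR all read as control regions for topology comparison
  nm <- ifelse(f$category == "control", "CR", f$name)
  tok <- paste(nm, f$strand, sep = "/")
  if (use_copy) tok <- paste(tok, f$copy, sep = "/")
  tok
}

#' Rotation-invariant equality of circular arrangements
#'
#' Two arrangements are equal when some rotation of one matches the other's
#' name+strand sequence exactly.  Spacers are ignored by default; copy tags
#' are ignored for monomers; CR/CR1/CR2 compare as control regions.
#'
#' @param a,b `mito_arrangement` objects, both monomeric or both dimeric.
#' @param include_spacers compare spacer features too (with provenance
#'   ignored).
#' @return logical.
#' @examples
#' arrangements_equal(bothid_fixture("G.p"), bothid_fixture("A.t"))  # TRUE
#' @export
arrangements_equal <- function(a, b, include_spacers = FALSE) {
  stopifnot(inherits(a, "mito_arrangement"), inherits(b, "mito_arrangement"))
  if (isTRUE(a$is_dimer) != isTRUE(b$is_dimer)) {
    stop("cannot compare a monomer with a dimer")
  }
  use_copy <- isTRUE(a$is_dimer)
  ta <- .equality_tokens(a, include_spacers, use_copy)
  tb <- .equality_tokens(b, include_spacers, use_copy)
  n <- length(ta)
  if (n != length(tb)) return(FALSE)
  if (n == 0L) return(TRUE)
  for (k in seq_len(n)) {
    if (identical(ta, tb[c(k:n, seq_len(k - 1L))[seq_len(n)]])) return(TRUE)
  }
  FALSE
}

#' Extract the gene-only circular order
#'
#' @param x a `mito_arrangement`.
#' @return data frame of gene features (protein/rRNA/tRNA) in circular order.
#' @export
gene_order <- function(x) {
  x$features[is_gene_category(x$features$category), , drop = FALSE]
}

#' @export
print.mito_arrangement <- function(x, ...) {
  f <- x$features
  kind <- if (isTRUE(x$is_dimer)) "dimeric" else "monomeric"
  ngene <- sum(is_gene_category(f$category))
  cat(sprintf("Circular %s mitochondrial arrangement: %d features (%d genes)\n",
              kind, nrow(f), ngene))
  if (nrow(f) > 0L) {
    lab <- ifelse(f$strand == "L" & is_gene_category(f$category),
                  paste0("-", f$name), f$name)
    lab <- ifelse(f$copy == "prime", paste0(lab, "'"), lab)
    cat(strwrap(paste(lab, collapse = " "), width = 76, indent = 2,
                exdent = 2), sep = "\n")
    cat(sprintf("  (linearized at %s; '-' marks L-strand genes)\n",
                f$name[1]))
  }
  invisible(x)
}
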