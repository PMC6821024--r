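# Rearrangement-type classification.
#
# The four bothid variants are distinguished by the layout of the control
# region(s), tRNA-D and the 8-gene L-strand cluster in the region between
# tRNA-T and tRNA-F:
#   Type I   : D - CR - (Q A C Y S1 ND6 E P)
#   Type II  : CR - (Q A C Y S1) - D - (ND6 E P)
#   Type III : CR - (Q A C Y S1) - D - (ND6 E P) - CR
#   Type IV  : (Q A C Y S1) - D - (ND6 E P) - CR
# plus the ancestral order itself.  Spacers and the O_L position are ignored
# (typing is gene/CR topology only); the cluster check requires the exact
# order, so any novel permutation is reported as "unclassified".

.type_templates <- list(
  I   = c("D", "CR", "Q", "A", "C", "Y", "S1", "ND6", "E", "P"),
  II  = c("CR", "Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P"),
  III = c("CR", "Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P", "CR"),
  IV  = c("Q", "A", "C", "Y", "S1", "D", "ND6", "E", "P", "CR"))

.h_block_template <- c("F", "12S", "V", "16S", "L1", "ND1", "I", "M", "ND2",
                       "W", "N", "COI", "COII", "K", "ATP8", "ATP6", "COIII",
                       "G", "ND3", "R", "ND4L", "ND4", "H", "S2", "L2",
                       "ND5", "CytB", "T")

#' Longest contiguous run of L-strand genes
#'
#' Scans the circular gene-only order (control regions, O_L and spacers
#' dropped) for the longest run of consecutive L-strand genes.  In a DMNL
#' product this is the 8-gene cluster Q-A-C-Y-S1-ND6-E-P (with tRNA-D
#' breaking it into 5+3 when translocated inside); in the ancestral order it
#' is the A-N-C-Y run of the WANCY neighborhood.
#'
#' @param a a monomeric `mito_arrangement`.
#' @return character vector of the gene names in the run (possibly empty).
#' @export
longest_l_strand_run <- function(a) {
  g <- gene_order(a)
  n <- nrow(g)
  if (n == 0L || all(g$strand == "H")) return(character())
  if (all(g$strand == "L")) return(g$name)
  is_l <- g$strand == "L"
  # rotate so position 1 is an H gene, then take runs
  start <- which(!is_l)[1]
  idx <- ((seq_len(n) + start - 2L) %% n) + 1L
  r <- rle(is_l[idx])
  ends <- cumsum(r$lengths)
  li <- which(r$values)
  best <- li[which.max(r$lengths[li])]
  run <- (ends[best] - r$lengths[best] + 1L):ends[best]
  g$name[idx[run]]
}

#' Classify a gene order into a DMNL rearrangement type
#'
#' @param a a monomeric `mito_arrangement` containing all 37 genes.
#' @return an object of class `type_call`: list with `label` (`"I"`,
#'   `"II"`, `"III"`, `"IV"`, `"ancestral"` or `"unclassified"`),
#'   `d_inside_cluster`, `cr_count`, `v_shuffled` and `l_cluster` (the gene
#'   names of the maximal L-strand cluster between T and F).
#' @details Classification is invariant under rotation of the circular
#'   order.  Missing genes are reported and classification refused.
#' @examples
#' classify_arrangement(bothid_fixture("C.az"))$label  # "I"
#' @export
classify_arrangement <- function(a) {
  stopifnot(inherits(a, "mito_arrangement"))
  if (isTRUE(a$is_dimer)) stop("classification expects a monomer")
  g <- gene_order(a)
  need <- c(.protein_genes, .rrna_genes, .trna_genes)
  missing <- setdiff(need, g$name)
  if (length(missing) > 0L) {
    stop("cannot classify: missing gene(s) ",
         paste(missing, collapse = ", "))
  }
  f <- a$features[!a$features$category %in% c("spacer", "origin"), ,
                  drop = FALSE]
  nm <- .norm_name(f$name, f$category)
  n <- length(nm)
  rot <- function(v, i) v[((seq_along(v) + i - 2L) %% length(v)) + 1L]
  nm <- rot(nm, which(nm == "F")[1])          # linearize at tRNA-F

  v_shuffled <- {
    core <- nm[nm %in% c("12S", "V", "16S", "L1")]
    identical(core, c("12S", "16S", "V", "L1"))
  }
  ti <- which(nm == "T")[1]
  region <- if (ti < n) nm[(ti + 1L):n] else character()
  l_cluster <- longest_l_strand_run(a)

  canonical <- canonical_teleost_order()
  if (arrangements_equal(a, canonical)) {
    label <- "ancestral"
  } else {
    head_ok <- identical(nm[seq_len(ti)],
                         if (v_shuffled)
                           c("F", "12S", "16S", "V", "L1",
                             .h_block_template[-(1:5)])
                         else .h_block_template)
    label <- "unclassified"
    if (head_ok) {
      for (ty in names(.type_templates)) {
        if (identical(region, .type_templates[[ty]])) {
          label <- ty
          break
        }
      }
    }
  }
  structure(list(label = label,
                 d_inside_cluster = label %in% c("II", "III", "IV"),
                 cr_count = sum(a$features$category == "control"),
                 v_shuffled = v_shuffled,
                 l_cluster = l_cluster),
            class = "type_call")
}

#' @export
print.type_call <- function(x, ...) {
  cat(sprintf("Rearrangement type: %s (CRs: %d; tRNA-D %s the cluster%s)\n",
              x$label, x$cr_count,
              if (x$d_inside_cluster) "inside" else "outside",
              if (x$v_shuffled) "; tRNA-V shuffled" else ""))
  invisible(x)
}

#' Classify a set of gene orders
#'
#' @param arrangements named list of `mito_arrangement` objects (names are
#'   species labels).
#' @return data frame with one row per species (`species`, `label`,
#'   `d_inside_cluster`, `cr_count`, `v_shuffled`) and attribute
#'   `"summary"`: a table of per-label membership counts.
#' @examples
#' orders <- lapply(setNames(nm = names(bothid_species_codes())),
#'                  bothid_fixture)
#' classify_all(orders)
#' @export
classify_all <- function(arrangements) {
  if (length(arrangements) == 0L) {
    out <- data.frame(species = character(), label = character(),
                      d_inside_cluster = logical(), cr_count = integer(),
                      v_shuffled = logical(), stringsAsFactors = FALSE)
    attr(out, "summary") <- table(character())
    return(out)
  }
  calls <- lapply(arrangements, classify_arrangement)
  out <- data.frame(
    species = names(arrangements),
    label = vapply(calls, `[[`, character(1), "label"),
    d_inside_cluster = vapply(calls, `[[`, logical(1), "d_inside_cluster"),
    cr_count = vapply(calls, `[[`, integer(1), "cr_count"),
    v_shuffled = vapply(calls, `[[`, logical(1), "v_shuffled"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "summary") <- table(out$label)
  out
}
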