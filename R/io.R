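# Gene-order file I/O.
#
# Tabular format: one feature per line, tab-separated
#   NAME  STRAND(+/-)  CATEGORY  [PROVENANCE]  [LENGTH_BP]
# with '.' for absent optional fields, '#' comment lines, and a header line
#   #circular anchor=<NAME> [dimer]
# The serialized strand convention is +/- mapping to H/L (GenBank complement
# semantics).

#' Write a gene arrangement to a tabular file
#'
#' @param x a `mito_arrangement`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_arrangement()]
#' @export
write_arrangement <- function(x, path) {
  stopifnot(inherits(x, "mito_arrangement"))
  f <- x$features
  header <- sprintf("#circular anchor=%s%s", x$anchor,
                    if (isTRUE(x$is_dimer)) " dimer" else "")
  strand <- ifelse(f$strand == "H", "+", "-")
  prov <- ifelse(is.na(f$provenance), ".", f$provenance)
  len <- ifelse(is.na(f$length_bp), ".", as.character(f$length_bp))
  nm <- ifelse(f$copy == "prime", paste0(f$name, "'"), f$name)
  lines <- c(header, paste(nm, strand, f$category, prov, len, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene arrangement from a tabular file
#'
#' Errors (malformed line, unknown gene token, duplicate gene in a monomer)
#' are reported with the offending line number.
#'
#' @param path input file path in the format written by
#'   [write_arrangement()].
#' @return a `mito_arrangement`; `read_arrangement(write_arrangement(x))`
#'   reproduces `x` including spacers and provenance.
#' @export
read_arrangement <- function(path) {
  lines <- readLines(path)
  anchor <- "F"
  is_dimer <- FALSE
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("anchor=([^ \t]+)", ln))[[1]]
      if (length(m) == 2L) anchor <- m[2]
      if (grepl("\\bdimer\\b", ln)) is_dimer <- TRUE
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed line ", i, " in '", path, "': expected at least ",
           "NAME, STRAND, CATEGORY")
    }
    nm <- parts[1]
    copy <- "plain"
    if (grepl("'$", nm)) {
      copy <- "prime"
      nm <- sub("'$", "", nm)
    }
    if (!nm %in% feature_vocabulary()) {
      stop("unknown gene token '", parts[1], "' at line ", i, " of '",
           path, "'")
    }
    if (!parts[2] %in% c("+", "-")) {
      stop("malformed strand '", parts[2], "' at line ", i,
           " (expected + or -)")
    }
    prov <- if (length(parts) >= 4L && parts[4] != ".") parts[4] else NA_character_
    len <- if (length(parts) >= 5L && parts[5] != ".") as.integer(parts[5]) else NA_integer_
    recs[[length(recs) + 1L]] <- list(name = nm,
                                      strand = if (parts[2] == "+") "H" else "L",
                                      copy = copy, provenance = prov,
                                      length_bp = len, line = i)
  }
  if (length(recs) == 0L) {
    return(arrangement(new_features(), anchor = anchor, is_dimer = is_dimer))
  }
  f <- new_features(
    name = vapply(recs, `[[`, character(1), "name"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    copy = vapply(recs, `[[`, character(1), "copy"),
    provenance = vapply(recs, `[[`, character(1), "provenance"),
    length_bp = vapply(recs, `[[`, integer(1), "length_bp"))
  genes <- is_gene_category(f$category)
  key <- paste(f$name, f$copy)
  dup <- genes & duplicated(key) & !is_dimer
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate gene '", f$name[i], "' in monomer at line ",
         recs[[i]]$line, " of '", path, "'")
  }
  arrangement(f, anchor = anchor, is_dimer = is_dimer)
}

# Synonym table mapping GenBank product/gene qualifiers to the controlled
# vocabulary.  Matching is case-insensitive on a normalized token.
.genbank_synonyms <- local({
  syn <- c(
    "nad1" = "ND1", "nd1" = "ND1", "nad2" = "ND2", "nd2" = "ND2",
    "cox1" = "COI", "coi" = "COI", "co1" = "COI",
    "cytochrome c oxidase subunit i" = "COI",
    "cox2" = "COII", "coii" = "COII", "co2" = "COII",
    "cytochrome c oxidase subunit ii" = "COII",
    "cox3" = "COIII", "coiii" = "COIII", "co3" = "COIII",
    "cytochrome c oxidase subunit iii" = "COIII",
    "atp6" = "ATP6", "atpase 6" = "ATP6", "atp synthase f0 subunit 6" = "ATP6",
    "atp8" = "ATP8", "atpase 8" = "ATP8", "atp synthase f0 subunit 8" = "ATP8",
    "nad3" = "ND3", "nd3" = "ND3", "nad4l" = "ND4L", "nd4l" = "ND4L",
    "nad4" = "ND4", "nd4" = "ND4", "nad5" = "ND5", "nd5" = "ND5",
    "nad6" = "ND6", "nd6" = "ND6",
    "cytb" = "CytB", "cob" = "CytB", "cytochrome b" = "CytB",
    "12s ribosomal rna" = "12S", "12s rrna" = "12S", "rrns" = "12S",
    "s-rrna" = "12S", "small subunit ribosomal rna" = "12S",
    "16s ribosomal rna" = "16S", "16s rrna" = "16S", "rrnl" = "16S",
    "l-rrna" = "16S", "large subunit ribosomal rna" = "16S",
    "trna-phe" = "F", "trna-val" = "V", "trna-leu" = "L1",
    "trna-leu(uur)" = "L1", "trna-leu(cun)" = "L2",
    "trna-ile" = "I", "trna-gln" = "Q", "trna-met" = "M", "trna-trp" = "W",
    "trna-ala" = "A", "trna-asn" = "N", "trna-cys" = "C", "trna-tyr" = "Y",
    "trna-ser" = "S1", "trna-ser(ucn)" = "S1", "trna-ser(agy)" = "S2",
    "trna-asp" = "D", "trna-lys" = "K", "trna-gly" = "G", "trna-arg" = "R",
    "trna-his" = "H", "trna-glu" = "E", "trna-thr" = "T", "trna-pro" = "P",
    "d-loop" = "CR", "control region" = "CR", "rep_origin" = "OL",
    "ol" = "OL", "origin of l-strand replication" = "OL")
  syn
})

map_genbank_product <- function(token) {
  key <- tolower(trimws(token))
  if (key %in% names(.genbank_synonyms)) return(.genbank_synonyms[[key]])
  if (toupper(trimws(token)) %in% feature_vocabulary()) {
    return(toupper(trimws(token)))
  }
  NA_character_
}

#' Read a gene arrangement from a GenBank flat-file feature table
#'
#' Minimal reader for user-supplied GenBank records: scans the FEATURES
#' block for `CDS`, `tRNA`, `rRNA`, `D-loop` and `rep_origin` entries,
#' maps `/product` and `/gene` qualifiers to the controlled vocabulary via a
#' bundled synonym table, and orders features by their start coordinate.
#' `complement(...)` locations map to the L-strand.
#'
#' @param path path to a GenBank flat file.
#' @param drop_unknown drop features whose product cannot be mapped instead
#'   of erroring.
#' @return a `mito_arrangement` monomer.
#' @export
read_genbank_arrangement <- function(path, drop_unknown = TRUE) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("no FEATURES block in '", path, "'")
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
  block <- lines[(fstart[1] + 1L):(fend - 1L)]
  keep_kinds <- c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin")
  feats <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    token <- cur$product
    if (is.na(token) && cur$kind == "D-loop") token <- "D-loop"
    if (is.na(token) && cur$kind == "rep_origin") token <- "rep_origin"
    nm <- if (is.na(token)) NA_character_ else map_genbank_product(token)
    c(cur, list(name = nm))
  }
  for (ln in block) {
    m <- regexec("^ {2,8}([A-Za-z_'-]+) +(complement\\()?[<>]?(\\d+)\\.\\.[<>]?(\\d+)",
                 ln)[[1]]
    if (m[1] != -1L) {
      parts <- regmatches(ln, list(m))[[1]]
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- flush(cur)
      cur <- if (parts[2] %in% keep_kinds) {
        list(kind = parts[2],
             strand = if (nzchar(parts[3])) "L" else "H",
             start = as.integer(parts[4]), end = as.integer(parts[5]),
             product = NA_character_)
      } else NULL
      next
    }
    if (!is.null(cur)) {
      q <- regmatches(ln, regexec("/(product|gene)=\"([^\"]+)\"", ln))[[1]]
      if (length(q) == 3L && is.na(cur$product)) cur$product <- q[3]
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- flush(cur)
  feats <- Filter(Negate(is.null), feats)
  if (length(feats) == 0L) stop("no usable features found in '", path, "'")
  nm <- vapply(feats, function(f) f$name, character(1))
  if (anyNA(nm)) {
    if (!drop_unknown) {
      stop("unmapped feature product(s) in '", path, "'")
    }
    feats <- feats[!is.na(nm)]
    nm <- nm[!is.na(nm)]
  }
  # two tRNA-Ser / tRNA-Leu isoacceptors: disambiguate by canonical context
  # (the second occurrence along the genome gets the S2/L2 label only if the
  # first was already seen and the synonym was ambiguous "trna-ser"/"trna-leu")
  for (pair in list(c("S1", "S2"), c("L1", "L2"))) {
    hits <- which(nm == pair[1])
    if (length(hits) == 2L) nm[hits[2]] <- pair[2]
  }
  ord <- order(vapply(feats, function(f) f$start, integer(1)))
  feats <- feats[ord]
  nm <- nm[ord]
  strand <- vapply(feats, function(f) f$strand, character(1))
  len <- vapply(feats, function(f) f$end - f$start + 1L, integer(1))
  cat_ <- feature_category(nm)
  strand[!is_gene_category(cat_)] <- "H"   # convention for CR/OL
  arrangement(new_features(nm, strand, length_bp = len))
}
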