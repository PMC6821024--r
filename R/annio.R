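# FASTA / GFF3 I/O for annotated synthetic genomes.

.gff_type <- function(category) {
  c(protein = "CDS", rRNA = "rRNA", tRNA = "tRNA", control = "D_loop",
    origin = "rep_origin", spacer = "region")[category]
}

#' Write an annotated sequence as FASTA plus GFF3
#'
#' @param x an `annotated_sequence`.
#' @param fasta,gff output paths.
#' @param name sequence record name (default `"genome"`).
#' @return invisibly, a list of the written paths.
#' @export
write_annotated <- function(x, fasta, gff, name = "genome") {
  stopifnot(inherits(x, "annotated_sequence"))
  ss <- Biostrings::DNAStringSet(stats::setNames(x$seq, name))
  Biostrings::writeXStringSet(ss, fasta)
  f <- x$features
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(f$strand == "H", "+", "-"))
  gr$type <- unname(.gff_type(f$category))
  gr$Name <- f$name
  gr$copy <- f$copy
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(list(fasta = fasta, gff = gff))
}

#' Read an annotated sequence from FASTA plus GFF3
#'
#' Counterpart of [write_annotated()]; ground truth is not serialized and
#' comes back empty.
#'
#' @param fasta,gff input paths.
#' @return an `annotated_sequence`.
#' @export
read_annotated <- function(fasta, gff) {
  ss <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff, format = "gff3")
  nm <- as.character(gr$Name)
  copy <- if (!is.null(gr$copy)) as.character(gr$copy)
          else rep("plain", length(gr))
  feats <- data.frame(
    name = nm,
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "L", "H"),
    category = feature_category(nm),
    copy = copy,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  new_annotated(as.character(ss[[1]]), feats)
}

#' Write generator ground truth as key-value text
#'
#' @param x an `annotated_sequence` carrying `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "annotated_sequence"))
  gt <- x$ground_truth
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(gt$params)) {
    writeLines(sprintf("seed=%d", gt$params$seed), con)
    writeLines(sprintf("ol_mode=%s", gt$params$ol_mode), con)
  }
  if (!is.null(gt$config)) {
    writeLines(sprintf("type=%s", gt$config$type_label), con)
  }
  if (!is.null(gt$remnants) && nrow(gt$remnants) > 0L) {
    writeLines("# remnants: source copy left right remnant_len", con)
    r <- gt$remnants
    writeLines(sprintf("remnant=%s\t%s\t%s\t%s\t%d", r$source, r$copy,
                       r$left, r$right, r$remnant_len), con)
  }
  invisible(path)
}
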