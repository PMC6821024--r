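# Sequence-level detectors: O_L-like stem-loops, conserved motifs, tandem
# repeats and the TAS core.
#
# Hairpin scoring is combinatorial (stem length, then mismatches), not
# thermodynamic: the published O_L structures are short canonical stems, so
# a base-pairing heuristic suffices and can be validated against a
# brute-force oracle.  G.U pairs are allowed in stems by default (the
# structure functions at the RNA/primer level) but counted separately.

.wc_pairs <- c("AT", "TA", "GC", "CG")
.gu_pairs <- c("GT", "TG")

.check_nt <- function(seq) {
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) {
    stop("non-nucleotide characters in sequence")
  }
  s
}

#' Find the best stem-loop (hairpin) in a sequence
#'
#' Scans every framing of a stem-loop with stem length at least `min_stem`,
#' loop length in `[min_loop, max_loop]` and at most `max_mismatch`
#' internal mismatches; the outermost and innermost stem pairs must be real
#' pairs (Watson-Crick or, when `allow_gu`, G.U).  The best hairpin
#' maximizes stem length, then minimizes mismatches, then lies leftmost.
#'
#' @param seq nucleotide string (A/C/G/T, case-insensitive).
#' @param min_stem minimal stem length in base pairs (default 8).
#' @param max_stem stem-length search cap (default 16; published O_L stems
#'   are well under this).
#' @param min_loop,max_loop loop length bounds in nt (defaults 3 and 15).
#' @param max_mismatch maximal internal mismatches in the stem (default 1).
#' @param allow_gu allow G.U wobble pairs in the stem (default `TRUE`).
#' @return a `hairpin` object (fields `start`, `end` 0-based half-open over
#'   the full extent, `stem_len_bp`, `loop_len_nt`, `mismatches`,
#'   `gu_pairs`, `motif5`, `motif3`, `mode`, `trnaN_bases_used`) or `NULL`
#'   when no qualifying hairpin exists.
#' @examples
#' find_hairpin("GGGCCGGGAATTTCCCGGCCC", min_stem = 8)
#' @export
find_hairpin <- function(seq, min_stem = 8L, max_stem = 16L, min_loop = 3L,
                         max_loop = 15L, max_mismatch = 1L, allow_gu = TRUE) {
  s <- .check_nt(seq)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < 2L * min_stem + min_loop) return(NULL)
  ok_pairs <- c(.wc_pairs, if (allow_gu) .gu_pairs)
  kmax <- min((n - min_loop) %/% 2L, max_stem)
  for (k in seq(kmax, min_stem)) {
    best <- NULL
    for (i in seq_len(n - 2L * k - min_loop + 1L)) {
      for (loop in seq(min_loop, min(max_loop, n - i + 1L - 2L * k))) {
        j <- i + k + loop              # start of stem2
        p1 <- v[i:(i + k - 1L)]
        p2 <- v[(j + k - 1L):j]        # reversed
        pr <- paste0(p1, p2)
        paired <- pr %in% ok_pairs
        if (!paired[1L] || !paired[k]) next
        mm <- sum(!paired)
        if (mm > max_mismatch) next
        gu <- sum(pr %in% .gu_pairs)
        if (is.null(best) || mm < best$mismatches) {
          best <- new_hairpin(start = i - 1L, end = j + k - 1L,
                              stem_len_bp = k, loop_len_nt = loop,
                              mismatches = mm, gu_pairs = gu)
          if (mm == 0L) break
        }
      }
      if (!is.null(best) && best$mismatches == 0L) break
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

new_hairpin <- function(start, end, stem_len_bp, loop_len_nt, mismatches,
                        gu_pairs, motif5 = NA_character_,
                        motif3 = NA_character_, mode = NA_character_,
                        trnaN_bases_used = 0L) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 stem_len_bp = as.integer(stem_len_bp),
                 loop_len_nt = as.integer(loop_len_nt),
                 mismatches = as.integer(mismatches),
                 gu_pairs = as.integer(gu_pairs),
                 motif5 = motif5, motif3 = motif3, mode = mode,
                 trnaN_bases_used = as.integer(trnaN_bases_used)),
            class = "hairpin")
}

#' Dot-bracket sketch of a hairpin
#'
#' @param h a `hairpin`.
#' @return string of `(`, `.` and `)` over the hairpin extent (mismatched
#'   stem positions drawn as `.`).
#' @export
hairpin_structure <- function(h) {
  k <- h$stem_len_bp
  paste0(strrep("(", k), strrep(".", h$loop_len_nt), strrep(")", k))
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf(
    "Stem-loop at [%d,%d): stem %d bp (%d mismatch, %d G.U), loop %d nt\n",
    x$start, x$end, x$stem_len_bp, x$mismatches, x$gu_pairs, x$loop_len_nt))
  if (!is.na(x$mode)) {
    cat(sprintf("  formation mode: %s (tRNA-N bases used: %d)\n",
                x$mode, x$trnaN_bases_used))
  }
  if (!is.na(x$motif5) || !is.na(x$motif3)) {
    cat(sprintf("  flanking motifs: 5' %s, 3' %s\n",
                ifelse(is.na(x$motif5), "none", x$motif5),
                ifelse(is.na(x$motif3), "none", x$motif3)))
  }
  cat("  ", hairpin_structure(x), "\n", sep = "")
  invisible(x)
}

#' Annotate conserved motifs flanking a hairpin
#'
#' Looks for the conserved 5' motifs (GGTGG, the GGGGG seen in most bothids,
#' or the GCCGG of the wider flatfish set) within `window` nt upstream of
#' the stem, and for the 3' motif TAGA within `window` nt downstream.
#'
#' @param seq the sequence the hairpin was found in.
#' @param around a `hairpin` located within `seq`.
#' @param window flank width in nt (default 8).
#' @return the hairpin with `motif5`/`motif3` filled in (`NA` when absent).
#' @export
scan_motifs <- function(seq, around, window = 8L) {
  s <- .check_nt(seq)
  stopifnot(inherits(around, "hairpin"))
  up <- substr(s, max(1L, around$start - window + 1L), around$start)
  down <- substr(s, around$end + 1L, min(nchar(s), around$end + window))
  around$motif5 <- NA_character_
  for (m in c("GGTGG", "GGGGG", "GCCGG")) {
    if (grepl(m, up, fixed = TRUE)) {
      around$motif5 <- m
      break
    }
  }
  around$motif3 <- if (grepl("TAGA", down, fixed = TRUE)) "TAGA"
                   else NA_character_
  around
}

#' Detect the light-strand replication origin of an annotated genome
#'
#' Mode cascade mirroring how O_L forms in rearranged bothid mitogenomes:
#' \enumerate{
#'   \item search the tRNA-N to COI intergenic region alone
#'     (`"spacer_only"`);
#'   \item if nothing qualifies, extend the window by 3, then 4, then 5
#'     bases from the spacer-adjacent (3') end of tRNA-N
#'     (`"spacer_plus_trnaN_3prime"`);
#'   \item if still nothing, search a centered window inside tRNA-N
#'     (`"trnaN_middle"`, default 26 nt as in the *C. azureus*-like case).
#' }
#' The first qualifying hairpin wins; later steps are never consulted.
#' Flanking motifs are annotated with [scan_motifs()].  Coordinates are
#' genome coordinates (0-based half-open).
#'
#' The searched intergenic region runs from the 3' (spacer-adjacent) end of
#' tRNA-N to the next downstream gene — tRNA-C in the ancestral order, COI
#' in the rearranged bothid orders; an annotated O_L feature inside that
#' region is part of the searchable window.
#'
#' @param annotated an `annotated_sequence` containing a tRNA-N feature.
#' @param copy which copy's WANCY neighborhood to inspect in a dimer
#'   (default `"plain"`).
#' @param middle_window width of the tRNA-N middle window (default 26).
#' @param ... hairpin parameters passed to [find_hairpin()].
#' @return a `hairpin` with `mode` and `trnaN_bases_used` set, or `NULL`.
#' @export
detect_ol <- function(annotated, copy = "plain", middle_window = 26L, ...) {
  stopifnot(inherits(annotated, "annotated_sequence"))
  f <- annotated$features[order(annotated$features$start), , drop = FALSE]
  s <- annotated$seq
  ni <- which(f$name == "N" & f$copy == copy)
  if (length(ni) != 1L) {
    stop("annotated genome must contain tRNA-N (copy '", copy, "')")
  }
  genes <- which(is_gene_category(f$category))
  after <- genes[genes > ni]
  if (length(after) == 0L) stop("no gene downstream of tRNA-N")
  ci <- after[1]
  # region between the end of tRNA-N and the next gene (no wrap in
  # generated genomes: the region never spans the origin)
  a <- f$end[ni]
  b <- f$start[ci]
  if (b < a) stop("tRNA-N/COI region wraps the origin; re-anchor the genome")
  region <- function(from) substr(s, from + 1L, b)
  finish <- function(h, offset, mode, used) {
    h$start <- h$start + offset
    h$end <- h$end + offset
    h$mode <- mode
    h$trnaN_bases_used <- used
    scan_motifs(s, h)
  }
  h <- find_hairpin(region(a), ...)
  if (!is.null(h)) return(finish(h, a, "spacer_only", 0L))
  for (k in 3:5) {
    h <- find_hairpin(region(a - k), ...)
    if (!is.null(h)) {
      return(finish(h, a - k, "spacer_plus_trnaN_3prime", k))
    }
  }
  len_n <- f$end[ni] - f$start[ni]
  if (len_n >= middle_window) {
    off <- f$start[ni] + (len_n - middle_window) %/% 2L
    h <- find_hairpin(substr(s, off + 1L, off + middle_window), ...)
    if (!is.null(h)) return(finish(h, off, "trnaN_middle", middle_window))
  }
  NULL
}

#' Find maximal tandem-repeat arrays
#'
#' Detects tandem arrays by period autocorrelation (positions matching the
#' position one period downstream) with exact extension; overlapping calls
#' are resolved longest-span-first (smaller period wins a tie, so a pure
#' array is reported at its primitive period).
#'
#' @param seq nucleotide string.
#' @param min_period minimal motif length (default 10).
#' @param min_copies minimal copy number, possibly fractional (default 3).
#' @return data frame with columns `motif`, `period_bp`, `copies` (one
#'   decimal), `start`, `end` (0-based half-open), ordered longest-first.
#' @examples
#' find_tandem_repeats(strrep("ACGTACGTACGTAC", 3), min_period = 10)
#' @export
find_tandem_repeats <- function(seq, min_period = 10L, min_copies = 3L) {
  s <- .check_nt(seq)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  empty <- data.frame(motif = character(), period_bp = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  pmax_ <- n %/% 2L
  if (pmax_ < min_period) return(empty)
  hits <- list()
  for (p in seq(min_period, pmax_)) {
    eq <- v[seq_len(n - p)] == v[seq(p + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (ri in which(r$values)) {
      len <- r$lengths[ri]
      span <- len + p
      if (span / p < min_copies) next
      start <- ends[ri] - len            # 0-based start of the array
      hits[[length(hits) + 1L]] <-
        data.frame(motif = substr(s, start + 1L, start + p),
                   period_bp = p, copies = round(span / p, 1),
                   start = start, end = start + span,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)
  hits <- hits[order(-(hits$end - hits$start), hits$period_bp, hits$start), ]
  keep <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    sel <- which(keep)
    clash <- any(hits$start[i] < hits$end[sel] &
                   hits$end[i] > hits$start[sel])
    if (!clash) keep[i] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for the TAS core motif
#'
#' Reports every match of the termination-associated-sequence core
#' ACAT-n-TGTA (the variable middle base is most often C in bothid control
#' regions) with the observed middle base.
#'
#' @param seq nucleotide string.
#' @return data frame with columns `pos` (0-based match start) and
#'   `middle` (the observed wildcard base).
#' @examples
#' scan_tas("ACATCTGTA")
#' @export
scan_tas <- function(seq) {
  s <- .check_nt(seq)
  n <- nchar(s)
  pos <- integer()
  middle <- character()
  if (n >= 9L) {
    for (i in seq_len(n - 8L)) {
      w <- substr(s, i, i + 8L)
      if (substr(w, 1L, 4L) == "ACAT" && substr(w, 6L, 9L) == "TGTA") {
        pos <- c(pos, i - 1L)
        middle <- c(middle, substr(w, 5L, 5L))
      }
    }
  }
  data.frame(pos = pos, middle = middle, stringsAsFactors = FALSE)
}
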