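# Synthetic annotated mitogenomes with recorded ground truth.
#
# The generator realizes any gene arrangement as a nucleotide sequence:
# genes get random sequences of realistic lengths (no codon structure —
# annotation realism is not a goal), control regions carry a TAS core and a
# 3' tandem-repeat array, and the tRNA-N/COI neighborhood carries a
# plantable O_L hairpin in any of the three formation modes.  Degeneration
# is simulated by truncating every DMNL-degenerated gene to a remnant slice
# of itself, so remnants are positionally (and in principle sequence-)
# traceable to their sources.  Every random choice flows from the mandatory
# seed; the same seed gives identical output.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# uniform integer on [lo, hi], safe for lo == hi
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Canonical gene-length table
#'
#' Approximate lengths (bp) of vertebrate mitochondrial protein-coding and
#' rRNA genes, chosen so a monomer lands near 16-17 kb.
#'
#' @return named integer vector.
#' @export
canonical_gene_lengths <- function() {
  c("12S" = 950L, "16S" = 1700L, ND1 = 975L, ND2 = 1045L, COI = 1550L,
    COII = 690L, ATP8 = 165L, ATP6 = 685L, COIII = 785L, ND3 = 350L,
    ND4L = 295L, ND4 = 1380L, ND5 = 1840L, ND6 = 520L, CytB = 1140L)
}

#' Parameters for the synthetic-genome generator
#'
#' Defaults state the emulated world: tRNAs 65-75 bp, protein/rRNA lengths
#' from [canonical_gene_lengths()], control regions of 900 bp carrying a TAS
#' core (ACATCTGTA) and 35 copies of a 22 bp tandem motif at the 3' end,
#' DMNL remnants uniform on 2-88 bp with degenerated control regions leaving
#' 155-511 bp remnants, and an O_L hairpin of 8 bp stem.
#'
#' @param seed integer seed; mandatory for reproducibility.
#' @param trna_len_range sampled tRNA gene length range.
#' @param gene_lengths named lengths for protein/rRNA genes.
#' @param cr_len control-region length (bp).
#' @param ol_mode hairpin formation mode to plant: `"spacer_only"`,
#'   `"spacer_plus_trnaN_3prime"` or `"trnaN_middle"`.
#' @param hairpin_stem,hairpin_loop planted stem/loop sizes (bp/nt).
#' @param trnaN_bases bases borrowed from the 3' end of tRNA-N in the
#'   borrow mode (3-5).
#' @param motif5,motif3 conserved motifs planted at the hairpin flanks.
#' @param middle_window tRNA-N middle window width for `"trnaN_middle"`.
#' @param middle_spacer_len N-COI gap left in the middle mode (the short
#'   7 bp spacer of the *C. azureus*-like genomes).
#' @param n_coi_filler extra spacer sequence 3' of the hairpin (fills the
#'   N-COI region to ~40 bp in the borrow mode).
#' @param spacer_len_range remnant length range for degenerated genes.
#' @param long_remnant_range remnant length range for a degenerated control
#'   region.
#' @param p_disappear probability a degenerated gene disappears entirely.
#' @param plant_repeats plant the CR tandem-repeat array.
#' @param repeat_motif_len,repeat_copies tandem array geometry.
#' @param tas_offset offset of the TAS core from the CR 5' end.
#' @param gc GC fraction of random sequence.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(seed,
                         trna_len_range = c(65L, 75L),
                         gene_lengths = canonical_gene_lengths(),
                         cr_len = 900L,
                         ol_mode = c("spacer_only",
                                     "spacer_plus_trnaN_3prime",
                                     "trnaN_middle"),
                         hairpin_stem = 8L, hairpin_loop = 5L,
                         trnaN_bases = 4L,
                         motif5 = "GGTGG", motif3 = "TAGA",
                         middle_window = 26L, middle_spacer_len = 7L,
                         n_coi_filler = 18L,
                         spacer_len_range = c(2L, 88L),
                         long_remnant_range = c(155L, 511L),
                         p_disappear = 0.15,
                         plant_repeats = TRUE,
                         repeat_motif_len = 22L, repeat_copies = 35L,
                         tas_offset = 20L,
                         gc = 0.45) {
  if (missing(seed)) stop("seed is mandatory")
  ol_mode <- match.arg(ol_mode)
  if (trnaN_bases < 3L || trnaN_bases > 5L) {
    stop("trnaN_bases must be 3-5")
  }
  stopifnot(trna_len_range[1] <= trna_len_range[2],
            spacer_len_range[1] <= spacer_len_range[2],
            cr_len > tas_offset + 9L +
              (if (plant_repeats) repeat_motif_len * repeat_copies else 0L) + 10L)
  structure(list(seed = as.integer(seed), trna_len_range = trna_len_range,
                 gene_lengths = gene_lengths, cr_len = cr_len,
                 ol_mode = ol_mode, hairpin_stem = hairpin_stem,
                 hairpin_loop = hairpin_loop, trnaN_bases = trnaN_bases,
                 motif5 = motif5, motif3 = motif3,
                 middle_window = middle_window,
                 middle_spacer_len = middle_spacer_len,
                 n_coi_filler = n_coi_filler,
                 spacer_len_range = spacer_len_range,
                 long_remnant_range = long_remnant_range,
                 p_disappear = p_disappear, plant_repeats = plant_repeats,
                 repeat_motif_len = repeat_motif_len,
                 repeat_copies = repeat_copies, tas_offset = tas_offset,
                 gc = gc),
            class = "synth_params")
}

# a perfect planted hairpin block with non-pairing guards:
#   [motif5] AA [stem1] A..A-loop [stem2] CC [motif3]
# the AA/CC buffers and A...A loop ends cannot pair, and any framing that
# reaches past them into the motifs accumulates at least two internal
# mismatches, so the detector (max_mismatch <= 1) sees exactly the planted
# stem length
make_hairpin_block <- function(p, stem = p$hairpin_stem,
                               loop = p$hairpin_loop) {
  stem1 <- rand_dna(stem, p$gc)
  loop_seq <- if (loop >= 2L) {
    paste0("A", rand_dna(loop - 2L, p$gc), "A")
  } else rand_dna(loop, p$gc)
  core <- paste0(stem1, loop_seq, revcomp(stem1))
  list(block = paste0(p$motif5, "AA", core, "CC", p$motif3),
       core = core,
       core_offset = nchar(p$motif5) + 2L,   # 0-based offset of stem within block
       stem = stem, loop = loop)
}

# control-region sequence with TAS core and optional 3' tandem array;
# flanks of the array are guarded against partial-copy extension
make_cr_seq <- function(p) {
  tas <- "ACATCTGTA"
  if (!p$plant_repeats) {
    body <- rand_dna(p$cr_len - p$tas_offset - nchar(tas), p$gc)
    return(list(seq = paste0(rand_dna(p$tas_offset, p$gc), tas, body),
                repeat_start = NA_integer_, motif = NA_character_))
  }
  repeat {
    motif <- rand_dna(p$repeat_motif_len, p$gc)
    v <- strsplit(motif, "")[[1]]
    periodic <- any(vapply(seq_len(p$repeat_motif_len - 1L), function(q)
      all(v[seq_len(p$repeat_motif_len - q)] == v[seq(q + 1L, p$repeat_motif_len)]),
      logical(1)))
    if (!periodic) break
  }
  array <- strrep(motif, p$repeat_copies)
  alen <- nchar(array)
  tail_len <- 10L
  mid_len <- p$cr_len - p$tas_offset - nchar(tas) - alen - tail_len
  repeat {
    mid <- rand_dna(mid_len, p$gc)
    if (substr(mid, mid_len, mid_len) !=
        substr(motif, p$repeat_motif_len, p$repeat_motif_len)) break
  }
  repeat {
    tail_seq <- rand_dna(tail_len, p$gc)
    if (substr(tail_seq, 1L, 1L) != substr(motif, 1L, 1L)) break
  }
  list(seq = paste0(rand_dna(p$tas_offset, p$gc), tas, mid, array, tail_seq),
       repeat_start = p$tas_offset + nchar(tas) + mid_len,  # 0-based in CR
       motif = motif)
}

new_annotated <- function(seq, features, ground_truth = list()) {
  structure(list(seq = seq, features = features,
                 ground_truth = ground_truth),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("Annotated mitogenome sequence: %d bp, %d features\n",
              nchar(x$seq), nrow(x$features)))
  invisible(x)
}

#' Extract the gene order of an annotated sequence
#'
#' @param annotated an `annotated_sequence`.
#' @param keep_spacers keep SPACER features (default drop).
#' @return a `mito_arrangement` in coordinate order.
#' @export
as_arrangement <- function(annotated, keep_spacers = FALSE) {
  f <- annotated$features[order(annotated$features$start), , drop = FALSE]
  if (!keep_spacers) f <- f[f$name != "SPACER", , drop = FALSE]
  arrangement(new_features(f$name, f$strand, copy = f$copy,
                           length_bp = f$end - f$start),
              is_dimer = any(f$copy == "prime"))
}

# single realization pass; returns an annotated_sequence or NULL when the
# planted O_L fails its own detection check (caller resamples)
.synth_once <- function(a, p) {
  f <- a$features
  n <- nrow(f)
  parts <- character(n)       # sequence of feature i
  gaps <- character(n)        # unannotated sequence after feature i
  ol_info <- list()
  drop_row <- rep(FALSE, n)
  for (i in seq_len(n)) {
    nm <- f$name[i]
    cat_ <- f$category[i]
    if (cat_ == "control") {
      cr <- make_cr_seq(p)
      parts[i] <- cr$seq
      ol_info[[paste0("cr_", i)]] <- cr
    } else if (cat_ == "origin") {
      if (p$ol_mode == "trnaN_middle") {
        drop_row[i] <- TRUE          # no separate O_L feature in this mode
      } else if (p$ol_mode == "spacer_only") {
        hp <- make_hairpin_block(p)
        parts[i] <- hp$block
        ol_info[[paste0("ol_", f$copy[i])]] <- hp
        gaps[i] <- rand_dna(p$n_coi_filler, p$gc)
      } else {
        # borrow mode: first trnaN_bases of the stem live in tRNA-N's tail;
        # the O_L feature holds the in-spacer remainder
        hp <- make_hairpin_block(p)
        b <- p$trnaN_bases
        head_len <- nchar(p$motif5) + 2L + b
        ol_info[[paste0("ol_", f$copy[i])]] <-
          c(hp, list(n_head = substr(hp$block, 1L, head_len)))
        parts[i] <- substr(hp$block, head_len + 1L, nchar(hp$block))
        gaps[i] <- rand_dna(p$n_coi_filler, p$gc)
      }
    } else if (cat_ == "spacer") {
      len <- f$length_bp[i]
      if (is.na(len)) {
        len <- sample_range(p$spacer_len_range[1], p$spacer_len_range[2])
      }
      parts[i] <- rand_dna(len, p$gc)
    } else if (cat_ == "tRNA") {
      len <- sample_range(p$trna_len_range[1], p$trna_len_range[2])
      parts[i] <- rand_dna(len, p$gc)
      if (nm == "N" && p$ol_mode == "trnaN_middle") {
        hp <- make_hairpin_block(p, stem = p$hairpin_stem,
                                 loop = p$middle_window - 2L * p$hairpin_stem)
        off <- (len - p$middle_window) %/% 2L +
          (p$middle_window - nchar(hp$core)) %/% 2L
        parts[i] <- paste0(substr(parts[i], 1L, off), hp$core,
                           substr(parts[i], off + nchar(hp$core) + 1L, len))
        ol_info[[paste0("mid_", f$copy[i])]] <- c(hp, list(n_offset = off))
        gaps[i] <- rand_dna(p$middle_spacer_len, p$gc)
      }
    } else {
      parts[i] <- rand_dna(unname(p$gene_lengths[[nm]]), p$gc)
    }
  }
  # borrow mode: append the hairpin head to tRNA-N (the copy preceding each
  # O_L feature)
  if (p$ol_mode == "spacer_plus_trnaN_3prime") {
    for (i in which(f$category == "origin")) {
      hp <- ol_info[[paste0("ol_", f$copy[i])]]
      ni <- which(f$name == "N" & f$copy == f$copy[i])
      parts[ni] <- paste0(parts[ni], hp$n_head)
    }
  }
  # assemble
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  chunks <- character(0)
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + nchar(parts[i])
    ends[i] <- pos
    chunks <- c(chunks, parts[i])
    if (nzchar(gaps[i])) {
      chunks <- c(chunks, gaps[i])
      pos <- pos + nchar(gaps[i])
    }
  }
  seq <- paste(chunks, collapse = "")
  feats <- data.frame(name = f$name, strand = f$strand,
                      category = f$category, copy = f$copy,
                      start = starts, end = ends,
                      stringsAsFactors = FALSE)
  feats <- feats[!drop_row, , drop = FALSE]
  rownames(feats) <- NULL
  gt <- list(params = p, ol = ol_info,
             planted = data.frame(name = f$name, copy = f$copy,
                                  start = starts, end = ends,
                                  stringsAsFactors = FALSE))
  new_annotated(seq, feats, gt)
}

# expected hairpin location for the planted mode, 0-based genome coords
planted_hairpin_coords <- function(annotated, p, copy = "plain") {
  f <- annotated$features
  if (p$ol_mode == "trnaN_middle") {
    ni <- which(f$name == "N" & f$copy == copy)
    hp <- annotated$ground_truth$ol[[paste0("mid_", copy)]]
    st <- f$start[ni] + hp$n_offset
    return(c(st, st + nchar(hp$core)))
  }
  oi <- which(f$name == "OL" & f$copy == copy)
  hp <- annotated$ground_truth$ol[[paste0("ol_", copy)]]
  if (p$ol_mode == "spacer_only") {
    st <- f$start[oi] + hp$core_offset
    return(c(st, st + nchar(hp$core)))
  }
  st <- f$start[oi] - p$trnaN_bases
  c(st, st + nchar(hp$core))
}

# does detection on the assembled genome reproduce the planted ground truth
# (mode, borrowed bases, exact site) for every monomer copy present?
.ol_check <- function(annotated, p) {
  want_mode <- p$ol_mode
  for (copy in unique(annotated$features$copy)) {
    h <- tryCatch(detect_ol(annotated, copy = copy), error = function(e) NULL)
    if (is.null(h)) return(FALSE)
    if (h$mode != want_mode) return(FALSE)
    if (want_mode == "spacer_plus_trnaN_3prime" &&
        h$trnaN_bases_used != p$trnaN_bases) return(FALSE)
    want <- planted_hairpin_coords(annotated, p, copy)
    if (h$start != want[1] || h$end != want[2]) return(FALSE)
  }
  TRUE
}

#' Realize a gene arrangement as an annotated nucleotide sequence
#'
#' Emits a sequence realizing the arrangement's feature order with sampled
#' lengths; control regions contain a TAS core and (when configured) a 3'
#' tandem array; the tRNA-N/COI neighborhood contains a plantable O_L
#' hairpin in the configured formation mode.  The generator
#' rejection-samples its random content until its own detector reproduces
#' the planted hairpin exactly, so the recorded ground truth is true by
#' construction.  Same seed, same output.
#'
#' @param a a `mito_arrangement` (monomeric or dimeric).
#' @param p a [synth_params()].
#' @return an `annotated_sequence` with `ground_truth` recording all
#'   placements.
#' @examples
#' g <- synth_sequence(bothid_fixture("G.p"), synth_params(seed = 1))
#' detect_ol(g)
#' @export
synth_sequence <- function(a, p) {
  stopifnot(inherits(a, "mito_arrangement"), inherits(p, "synth_params"))
  if (p$ol_mode != "trnaN_middle" &&
      !any(a$features$category == "origin") &&
      any(a$features$name == "N")) {
    stop("arrangement has no O_L feature; use ol_mode = 'trnaN_middle'")
  }
  with_seed(p$seed, {
    for (attempt in seq_len(50L)) {
      out <- .synth_once(a, p)
      if (!any(a$features$name == "N") || .ol_check(out, p)) return(out)
    }
    stop("could not realize a genome matching the planted O_L ground truth")
  })
}

#' Simulate DMNL degeneration at the sequence level
#'
#' Takes a synthetic dimer of the canonical order, runs the order-level DMNL
#' engine for `config`, and realizes the outcome in sequence: every
#' degenerated gene is truncated to a remnant slice of itself (length
#' sampled from `p$spacer_len_range`, or 0 with probability
#' `p$p_disappear`); a degenerated control region leaves a long remnant
#' (`p$long_remnant_range`) under `retain_one` and disappears under
#' `retain_one_full_loss`; the tRNA-D/tRNA-V moves are applied.  Ground
#' truth maps every degenerated gene to its remnant length and final locus.
#'
#' @param dimer_seq an `annotated_sequence` realizing the canonical dimer
#'   (from `synth_sequence(dimerize(canonical_teleost_order()), p)`).
#' @param config a [dmnl_config()].
#' @param p a [synth_params()] (its seed, offset by one, drives the
#'   degeneration sampling).
#' @return an `annotated_sequence` of the evolved monomer; SPACER features
#'   mark nonzero remnants; `ground_truth$remnants` records `source`,
#'   `copy`, `left`, `right` and `remnant_len` for every degenerated gene,
#'   and `ground_truth$result` keeps the engine's `dmnl_result`.
#' @export
evolve_degeneration <- function(dimer_seq, config, p) {
  stopifnot(inherits(dimer_seq, "annotated_sequence"),
            inherits(config, "dmnl_config"), inherits(p, "synth_params"))
  arr <- as_arrangement(dimer_seq)
  if (!isTRUE(arr$is_dimer)) stop("dimer_seq must realize a dimer")
  if (!arrangements_equal(arr, dimerize(canonical_teleost_order()))) {
    stop("dimer_seq must realize a dimer of the canonical teleost order")
  }
  res <- run_dmnl(canonical_teleost_order(), config)
  df <- dimer_seq$features
  feat_seq <- function(nm, copy) {
    i <- which(df$name == nm & df$copy == copy)
    if (length(i) != 1L) stop("cannot locate ", nm, " (", copy, ") in dimer")
    substr(dimer_seq$seq, df$start[i] + 1L, df$end[i])
  }
  orig_name <- function(nm) if (nm %in% .control_features) "CR" else nm
  with_seed(p$seed + 1L, {
    f <- res$with_spacers$features
    n <- nrow(f)
    loci <- refresh_loci(res)      # aligned with spacer rows in order
    sp_rows <- which(f$category == "spacer")
    parts <- character(n)
    rem_len <- integer(length(sp_rows))
    for (j in seq_along(sp_rows)) {
      i <- sp_rows[j]
      src <- loci$source[j]
      src_copy <- loci$copy[j]
      full <- feat_seq(orig_name(src), src_copy)
      flen <- nchar(full)
      len <- if (src %in% .control_features || src == "CR") {
        if (config$cr_mode == "retain_one_full_loss") 0L
        else sample_range(p$long_remnant_range[1],
                          min(p$long_remnant_range[2], flen))
      } else if (stats::runif(1) < p$p_disappear) 0L
      else sample_range(p$spacer_len_range[1],
                        min(p$spacer_len_range[2], flen))
      rem_len[j] <- len
      parts[i] <- if (len > 0L) {
        off <- sample.int(flen - len + 1L, 1L) - 1L
        substr(full, off + 1L, off + len)
      } else ""
    }
    for (i in setdiff(seq_len(n), sp_rows)) {
      parts[i] <- feat_seq(orig_name(f$name[i]), res$survivor_copy[[f$name[i]]])
    }
    keep <- nchar(parts) > 0L
    starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      starts[i] <- pos
      pos <- pos + nchar(parts[i])
      ends[i] <- pos
    }
    feats <- data.frame(name = f$name, strand = f$strand,
                        category = f$category, copy = "plain",
                        start = starts, end = ends,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(feats) <- NULL
    remnants <- data.frame(loci, remnant_len = rem_len,
                           stringsAsFactors = FALSE)
    new_annotated(paste(parts, collapse = ""), feats,
                  ground_truth = list(remnants = remnants, config = config,
                                      params = p, result = res))
  })
}
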