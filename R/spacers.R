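# Intergenic-spacer provenance tracing.
#
# Under DMNL every non-transcribed gene degenerates in place, so each
# intergenic spacer of a rearranged genome is predicted to sit between two
# specific surviving neighbors and to descend from specific source genes.
# Consecutive degenerated genes collapsing between the same survivors merge
# into one locus whose candidate source list holds them all (ambiguous
# provenance is represented, never resolved by guessing).

# Locus ids in the style of the published spacer census: ids 1-12 plus the
# primed ids for loci split by the translocated tRNA-D (6/6' outside the
# cluster in Type I, 10/10' inside it in Types II-IV).  Anchors that the
# census text fixes: 3 = the N/O_L-COI spacer, 12 = the long (155-511 bp)
# degenerated-CR remnant between P and F.  The rest is positional; loci not
# in the table get fresh x<k> labels.
.locus_id_table <- list(
  c("I", "M", "1"), c("W", "N", "2"),
  c("OL", "COI", "3"), c("N", "COI", "3"),
  c("COI", "COII", "4"), c("ND5", "CytB", "5"),
  c("T", "D", "6"), c("T", "CR", "6"), c("D", "CR", "6'"),
  c("CR", "Q", "7"), c("T", "Q", "7"),
  c("Q", "A", "8"), c("A", "C", "9"),
  c("S1", "D", "10"), c("S1", "ND6", "10"), c("D", "ND6", "10'"),
  c("E", "P", "11"), c("P", "F", "12"), c("P", "CR", "12"))

locus_id_for <- function(left, right) {
  for (row in .locus_id_table) {
    if (row[1] == left && row[2] == right) return(row[3])
  }
  NA_character_
}

# canonical-order gaps also present in non-rearranged flatfishes; these are
# not DMNL evidence and are excluded from the census
.unrelated_loci <- list(
  c("12S", "16S"), c("16S", "V"), c("V", "L1"),   # tRNA-V shuffle gaps
  c("H", "S2"),                                   # double-A spacer
  c("ND1", "I"), c("COIII", "G"), c("ATP8", "ATP6"))

#' Loci with no relationship to the DMNL process
#'
#' Intergenic gaps at these adjacencies occur in non-rearranged flatfishes
#' (or arise from the tRNA-V shuffle) and are excluded from the spacer
#' census.
#'
#' @return data frame with columns `left`, `right`.
#' @export
dmnl_unrelated_loci <- function() {
  data.frame(left = vapply(.unrelated_loci, `[`, character(1), 1),
             right = vapply(.unrelated_loci, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Predict intergenic-spacer loci from a DMNL variant
#'
#' Runs the DMNL engine and converts its degeneration record into spacer
#' traces: one row per locus between surviving neighbors, with all source
#' genes collapsing there merged into the candidate list, ordered along the
#' final arrangement.
#'
#' @param config a [dmnl_config()]; or a `dmnl_result` already produced by
#'   [run_dmnl()].
#' @return data frame of class `spacer_traces` with columns `locus_id`,
#'   `left`, `right`, `candidate_sources` (semicolon-joined gene names) and
#'   `observed_length_bp` (`NA` until matched).  The config is attached as
#'   attribute `"config"`.
#' @examples
#' predict_spacer_loci(dmnl_config("III"))
#' @export
predict_spacer_loci <- function(config) {
  res <- if (inherits(config, "dmnl_result")) config
         else run_dmnl(canonical_teleost_order(), config)
  f <- res$with_spacers$features
  n <- nrow(f)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (f$category[i] == "spacer") {
      j <- i
      while (j < n && f$category[j + 1L] == "spacer") j <- j + 1L
      left_i <- if (i == 1L) n else i - 1L      # anchored at F, never spacer
      right_i <- if (j == n) 1L else j + 1L
      src <- sub("'$", "", f$provenance[i:j])
      out[[length(out) + 1L]] <- data.frame(
        left = f$name[left_i], right = f$name[right_i],
        candidate_sources = paste(src, collapse = ";"),
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(left = character(), right = character(),
               candidate_sources = character(), stringsAsFactors = FALSE)
  norm_cr <- function(x) ifelse(x %in% .control_features, "CR", x)
  ids <- mapply(locus_id_for, norm_cr(out$left), norm_cr(out$right))
  fresh <- which(is.na(ids))
  if (length(fresh)) ids[fresh] <- paste0("x", seq_along(fresh))
  out <- data.frame(locus_id = unname(ids), out,
                    observed_length_bp = NA_integer_,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- res$config
  class(out) <- c("spacer_traces", "data.frame")
  out
}

# circular gap table of an annotated sequence: one row per adjacency of
# non-spacer features, with the summed length of everything between them
annotated_gaps <- function(annotated) {
  f <- annotated$features
  f <- f[order(f$start), , drop = FALSE]
  keep <- f$name != "SPACER"
  g <- f[keep, , drop = FALSE]
  n <- nrow(g)
  L <- nchar(annotated$seq)
  nxt <- c(2:n, 1L)
  gap <- (g$start[nxt] - g$end) %% L
  data.frame(left = g$name, right = g$name[nxt], gap_bp = as.integer(gap),
             stringsAsFactors = FALSE)
}

#' Match predicted spacer loci against an annotated genome
#'
#' Fills `observed_length_bp` for every predicted locus at which the
#' annotated genome shows an inter-feature gap of at least `min_len` (2 bp,
#' the shortest spacer reported in rearranged bothids); loci with no gap
#' keep `NA` (source gene fully disappeared).
#'
#' @param predicted traces from [predict_spacer_loci()].
#' @param annotated an `annotated_sequence` (see [synth_sequence()] or
#'   [evolve_degeneration()]) whose gene order classifies to the same type
#'   as the predicted config.
#' @param min_len minimal gap length counted as an observed spacer.
#' @return `predicted` with `observed_length_bp` filled in.
#' @export
match_observed <- function(predicted, annotated, min_len = 2L) {
  stopifnot(inherits(predicted, "spacer_traces"),
            inherits(annotated, "annotated_sequence"))
  cfg <- attr(predicted, "config")
  obs_type <- classify_arrangement(as_arrangement(annotated))$label
  if (!is.null(cfg) && !identical(obs_type, cfg$type_label)) {
    stop("gene-order mismatch: annotated genome classifies as '", obs_type,
         "' but traces were predicted for Type ", cfg$type_label)
  }
  gaps <- annotated_gaps(annotated)
  norm_cr <- function(x) ifelse(x %in% .control_features, "CR", x)
  gkey <- paste(norm_cr(gaps$left), norm_cr(gaps$right))
  pkey <- paste(norm_cr(predicted$left), norm_cr(predicted$right))
  hit <- match(pkey, gkey)
  len <- gaps$gap_bp[hit]
  predicted$observed_length_bp <-
    ifelse(!is.na(len) & len >= min_len, len, NA_integer_)
  predicted
}

#' Census of unique intergenic spacers
#'
#' A "unique spacer" is one per-species occurrence of an observed gap
#' (length >= the matching threshold) at a DMNL-predicted locus; loci at the
#' DMNL-unrelated adjacencies (see [dmnl_unrelated_loci()]) are excluded.
#'
#' @param traced named list: species -> matched traces from
#'   [match_observed()].
#' @return list with `per_species` (species, n_spacers), `per_locus`
#'   (locus_id, left, right, n_species, min_bp, max_bp, sources) and
#'   `n_unique` (total count of (species, locus) spacers).
#' @export
spacer_census <- function(traced) {
  unrelated <- paste(dmnl_unrelated_loci()$left, dmnl_unrelated_loci()$right)
  rows <- lapply(names(traced), function(sp) {
    tr <- traced[[sp]]
    tr <- tr[!paste(tr$left, tr$right) %in% unrelated, , drop = FALSE]
    tr <- tr[!is.na(tr$observed_length_bp), , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    data.frame(species = sp, tr, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  all <- if (length(rows)) do.call(rbind, rows) else NULL
  per_species <- data.frame(
    species = names(traced),
    n_spacers = vapply(names(traced), function(sp)
      if (is.null(all)) 0L else sum(all$species == sp), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(all) || nrow(all) == 0L) {
    per_locus <- data.frame(locus_id = character(), left = character(),
                            right = character(), n_species = integer(),
                            min_bp = integer(), max_bp = integer(),
                            sources = character(), stringsAsFactors = FALSE)
    return(list(per_species = per_species, per_locus = per_locus,
                n_unique = 0L))
  }
  key <- paste(all$left, all$right)
  per_locus <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- all[key == k, , drop = FALSE]
    data.frame(locus_id = sub$locus_id[1], left = sub$left[1],
               right = sub$right[1], n_species = nrow(sub),
               min_bp = min(sub$observed_length_bp),
               max_bp = max(sub$observed_length_bp),
               sources = paste(unique(unlist(
                 strsplit(sub$candidate_sources, ";", fixed = TRUE))),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_locus) <- NULL
  list(per_species = per_species, per_locus = per_locus,
       n_unique = nrow(all))
}
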