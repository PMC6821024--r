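# The Dimer-Mitogenome and Non-Random Loss (DMNL) engine.
#
# Mechanism: two monomers fuse head-to-tail into a circular dimer with two
# control regions (CRs), each hosting an H-strand and an L-strand
# transcription promoter (HSP/LSP and HSP'/LSP').  The promoter pair of one
# CR is lost by mutation; genes no longer covered by any functional
# transcription unit degenerate to intergenic spacers.  The exception is
# tRNA-N: the copy adjacent to the surviving COI is retained (its middle or
# 3' end supports the light-strand replication origin) even though it is the
# transcription-expected N' copy that is covered.  The surviving genes form
# a rearranged monomer.

#' DMNL variant configuration
#'
#' Parameterizes the four rearrangement variants observed in bothid
#' flatfishes.  All four share dimerization, loss of one CR's promoter pair
#' and non-random loss; they differ in control-region bookkeeping and in the
#' timing and target of the tRNA-D translocation:
#' \describe{
#'   \item{Type I}{single CR; D translocated outside the L-strand gene
#'     cluster, between tRNA-T and the CR.}
#'   \item{Type II}{single CR; D translocated inside the cluster, between S1
#'     and ND6.}
#'   \item{Type III}{both CRs persist (CR1 between T and Q, CR2 after P); D
#'     inside the cluster.}
#'   \item{Type IV}{the lost-promoter CR degenerates entirely, leaving only
#'     the CR after P; D inside the cluster.  `v_shuffle` additionally moves
#'     tRNA-V from 12S-V-16S to 16S-V-L1 (A. intermedius).}
#' }
#'
#' @param type_label `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param d_timing `"after"` (default) or `"before"`: whether the tRNA-D
#'   translocation happens after non-random loss or already in the monomer
#'   before dimerization.
#' @param v_shuffle shuffle tRNA-V (legal only with Type IV).
#' @param lost_promoters which promoter pair loses function; default the
#'   HSP/LSP pair of the CR preceding the prime copy.
#' @param cr_mode control-region bookkeeping; defaults to the type's mode
#'   (`"retain_one"` for I/II, `"retain_both"` for III,
#'   `"retain_one_full_loss"` for IV).
#' @param d_pre_target insertion locus (left/right neighbor names) for the
#'   `d_timing = "before"` pre-translocation; defaults to between T and P
#'   for Type I and between ND5 and ND6 for Types II-IV.
#' @return an object of class `dmnl_config`.
#' @seealso [run_dmnl()]
#' @export
dmnl_config <- function(type_label = c("I", "II", "III", "IV"),
                        d_timing = c("after", "before"),
                        v_shuffle = FALSE,
                        lost_promoters = c("HSP", "LSP"),
                        cr_mode = NULL,
                        d_pre_target = NULL) {
  type_label <- match.arg(type_label)
  d_timing <- match.arg(d_timing)
  if (v_shuffle && type_label != "IV") {
    stop("v_shuffle is legal only with Type IV")
  }
  pairs <- list(c("HSP", "LSP"), c("HSP_prime", "LSP_prime"))
  if (!any(vapply(pairs, setequal, logical(1), y = lost_promoters))) {
    stop("lost_promoters must be one CR's pair: {HSP, LSP} or ",
         "{HSP_prime, LSP_prime}")
  }
  if (is.null(cr_mode)) {
    cr_mode <- switch(type_label, I = "retain_one", II = "retain_one",
                      III = "retain_both", IV = "retain_one_full_loss")
  }
  cr_mode <- match.arg(cr_mode,
                       c("retain_one", "retain_both", "retain_one_full_loss"))
  d_target <- if (type_label == "I") c("T", "CR") else c("S1", "ND6")
  if (is.null(d_pre_target)) {
    d_pre_target <- if (type_label == "I") c("T", "P") else c("ND5", "ND6")
  }
  structure(list(type_label = type_label, d_timing = d_timing,
                 v_shuffle = v_shuffle, lost_promoters = lost_promoters,
                 cr_mode = cr_mode, d_target = d_target,
                 d_pre_target = d_pre_target),
            class = "dmnl_config")
}

#' @export
print.dmnl_config <- function(x, ...) {
  cat(sprintf(
    "DMNL config: Type %s (cr_mode=%s, tRNA-D %s DMNL%s; lost promoters: %s)\n",
    x$type_label, x$cr_mode, x$d_timing,
    if (x$v_shuffle) ", tRNA-V shuffled" else "",
    paste(x$lost_promoters, collapse = "+")))
  invisible(x)
}

#' Dimerize a monomeric arrangement
#'
#' Forms the head-to-tail dimer of two monomers: copy 1 keeps `copy =
#' "plain"`, copy 2 is tagged `"prime"`; gene order within each copy is
#' preserved, giving 74 genes, 2 CRs and 2 O_Ls for a canonical input.
#'
#' @param a a `mito_arrangement` monomer containing exactly one control
#'   region.
#' @return a dimeric `mito_arrangement`.
#' @export
dimerize <- function(a) {
  stopifnot(inherits(a, "mito_arrangement"))
  if (isTRUE(a$is_dimer)) stop("input is already a dimer")
  if (sum(a$features$category == "control") != 1L) {
    stop("dimerize expects a monomer with exactly one control region")
  }
  prime <- a$features
  prime$copy <- "prime"
  arrangement(rbind(a$features, prime), anchor = a$anchor, is_dimer = TRUE)
}

#' Promoters of a dimeric arrangement
#'
#' @param dimer a dimeric `mito_arrangement` with two CRs.
#' @param lost promoter ids whose `functional` flag is set to `FALSE`.
#' @return data frame with columns `id`, `strand`, `host_copy` (the copy tag
#'   of the hosting CR), `host_pos` (feature index of that CR) and
#'   `functional`.
#' @export
dimer_promoters <- function(dimer, lost = character()) {
  stopifnot(isTRUE(dimer$is_dimer))
  f <- dimer$features
  crs <- which(f$category == "control")
  if (length(crs) != 2L) stop("dimer must contain exactly two CRs")
  host_copy <- f$copy[crs]
  plain_cr <- crs[host_copy == "plain"][1]
  prime_cr <- crs[host_copy == "prime"][1]
  out <- data.frame(
    id = c("HSP", "LSP", "HSP_prime", "LSP_prime"),
    strand = c("H", "L", "H", "L"),
    host_copy = c("plain", "plain", "prime", "prime"),
    host_pos = c(plain_cr, plain_cr, prime_cr, prime_cr),
    stringsAsFactors = FALSE)
  out$functional <- !(out$id %in% lost)
  out
}

#' Transcription units of a dimeric arrangement
#'
#' For each functional promoter, the covered span runs from its host CR in
#' the strand's transcription direction to the first terminator encountered:
#' H-strand units run forward to the TAS of the next CR reached, L-strand
#' units run backward to the first tRNA-L1 copy.  A gene is transcribed iff
#' it lies on the unit's strand within some functional unit's span.
#'
#' @param dimer a dimeric `mito_arrangement`.
#' @param promoters data frame as returned by [dimer_promoters()].
#' @return list of units, each a list with `promoter_id`, `strand`,
#'   `covered` (feature indices in transcription order) and `transcribed`
#'   (indices of covered same-strand genes).
#' @export
transcription_units <- function(dimer, promoters) {
  stopifnot(isTRUE(dimer$is_dimer))
  f <- dimer$features
  n <- nrow(f)
  units <- list()
  for (i in which(promoters$functional)) {
    p <- promoters[i, ]
    step <- if (p$strand == "H") 1L else -1L
    pos <- p$host_pos
    covered <- integer()
    repeat {
      pos <- ((pos - 1L + step) %% n) + 1L
      covered <- c(covered, pos)
      if (length(covered) > n) stop("no terminator reachable from ", p$id)
      if (p$strand == "H" && f$category[pos] == "control") break
      if (p$strand == "L" && f$name[pos] == "L1") break
    }
    transcribed <- covered[f$strand[covered] == p$strand &
                             is_gene_category(f$category[covered])]
    units[[length(units) + 1L]] <-
      list(promoter_id = p$id, strand = p$strand, covered = covered,
           transcribed = transcribed)
  }
  units
}

# positions (indices into dimer features) of genes transcribed by any
# functional unit
transcribed_positions <- function(dimer, promoters) {
  units <- transcription_units(dimer, promoters)
  sort(unique(unlist(lapply(units, `[[`, "transcribed"))))
}

#' Non-random loss on a dimeric arrangement
#'
#' Applies the loss step of the DMNL mechanism: (1) computes the transcribed
#' gene set under the functional promoters, (2) marks every non-transcribed
#' gene degenerated, (3) applies the tRNA-N retention rule — the N copy
#' immediately upstream (H-sense) of the surviving COI is retained and the
#' other copy degenerates, together with the O_L adjacent to the retained N,
#' (4) handles CRs per `config$cr_mode`, and (5) converts degenerated
#' features to provenance-tagged spacers and clears copy tags.
#'
#' @param dimer a dimer produced by [dimerize()].
#' @param config a [dmnl_config()].
#' @return an object of class `dmnl_result`: list with `final` (monomeric
#'   `mito_arrangement`, spacers dropped), `with_spacers` (same order with
#'   SPACER features in place of degenerated genes), `degenerated` (data
#'   frame `source`, `copy`, `left`, `right` of surviving neighbors) and
#'   `event_log`.
#' @export
nonrandom_loss <- function(dimer, config) {
  stopifnot(isTRUE(dimer$is_dimer), inherits(config, "dmnl_config"))
  f <- dimer$features
  n <- nrow(f)
  promoters <- dimer_promoters(dimer, lost = config$lost_promoters)
  keep <- rep(FALSE, n)
  keep[transcribed_positions(dimer, promoters)] <- TRUE

  # tRNA-N retention: positional, anchored on the surviving COI copy
  coi <- which(f$name == "COI" & keep)
  if (length(coi) != 1L) stop("expected exactly one surviving COI copy")
  npos <- which(f$name == "N")
  if (length(npos) > 0L) {
    back_dist <- (coi - npos) %% n        # distance going upstream from COI
    retained_n <- npos[which.min(back_dist)]
    keep[npos] <- FALSE
    keep[retained_n] <- TRUE
    # retain the O_L adjacent to (immediately downstream of) the retained N
    ols <- which(f$category == "origin")
    if (length(ols) > 0L) {
      fwd_dist <- (ols - retained_n) %% n
      keep[ols] <- FALSE
      keep[ols[which.min(fwd_dist)]] <- TRUE
    }
  }

  # control-region bookkeeping
  crs <- which(f$category == "control")
  lost_copy <- if (setequal(config$lost_promoters, c("HSP", "LSP")))
    "plain" else "prime"
  lost_cr <- crs[f$copy[crs] == lost_copy]
  kept_cr <- setdiff(crs, lost_cr)
  keep[crs] <- switch(config$cr_mode,
    retain_both = TRUE,
    # the single CR of Types I/II sits between T and the L-strand cluster:
    # positionally this is the lost-promoter CR; the other degenerates
    retain_one = crs %in% lost_cr,
    retain_one_full_loss = crs %in% kept_cr)

  # record which physical copy survived under each final feature name
  # (final CR names are positional from the surviving tRNA-F)
  surv_idx <- which(keep)
  fF <- which(f$name == "F" & keep)[1]
  ord <- surv_idx[order((surv_idx - fF) %% n)]
  surv_names <- f$name[ord]
  crp <- which(f$category[ord] == "control")
  surv_names[crp] <- if (length(crp) == 2L) c("CR1", "CR2") else "CR"
  survivor_copy <- stats::setNames(as.list(f$copy[ord]), surv_names)

  degen <- which(!keep)
  spacers <- f[degen, , drop = FALSE]
  out <- f
  out$provenance[degen] <- ifelse(spacers$copy == "prime",
                                  paste0(spacers$name, "'"), spacers$name)
  out$name[degen] <- "SPACER"
  out$category[degen] <- "spacer"
  out$strand[degen] <- "H"
  src_copy <- out$copy
  out$copy <- "plain"

  with_spacers <- arrangement(out, anchor = dimer$anchor, is_dimer = FALSE)
  with_spacers <- rename_crs(with_spacers)
  degen_df <- refresh_loci(list(with_spacers = with_spacers))
  final_f <- with_spacers$features[with_spacers$features$category != "spacer", ,
                                   drop = FALSE]
  final <- arrangement(final_f, anchor = dimer$anchor, is_dimer = FALSE)

  log <- c(
    sprintf("lose-promoters: %s", paste(config$lost_promoters, collapse = "+")),
    sprintf("degenerate: %d features (%s)", length(degen),
            paste(out$provenance[degen], collapse = ", ")),
    sprintf("retain tRNA-N copy adjacent to surviving COI (%s copy)",
            src_copy[coi]))
  structure(list(final = final, with_spacers = with_spacers,
                 degenerated = degen_df, survivor_copy = survivor_copy,
                 event_log = log),
            class = "dmnl_result")
}

# After loss the surviving arrangement is a monomer: name its control
# regions positionally (two CRs: the first one forward of tRNA-F is CR1,
# the other CR2; a single CR is just CR).
rename_crs <- function(x) {
  f <- x$features
  crs <- which(f$category == "control")
  f$name[crs] <- if (length(crs) == 2L) c("CR1", "CR2") else "CR"
  # canonicalization anchors at F, so positional order along rows is the
  # forward order from F
  x$features <- f
  x
}

#' Run a full DMNL scenario
#'
#' Orchestrates: optional pre-translocation of tRNA-D (when `d_timing =
#' "before"`), dimerization, non-random loss, translocation of tRNA-D to the
#' type's target locus (when not already there), and the optional tRNA-V
#' shuffle.  The output classifies as the config's type label.
#'
#' @param start a monomeric `mito_arrangement` (normally
#'   [canonical_teleost_order()]).
#' @param config a [dmnl_config()].
#' @return a `dmnl_result` (see [nonrandom_loss()]) with the D/V moves
#'   applied to both `final` and `with_spacers` and logged in `event_log`.
#' @examples
#' res <- run_dmnl(canonical_teleost_order(), dmnl_config("III"))
#' arrangements_equal(res$final, bothid_fixture("G.p"))
#' @export
run_dmnl <- function(start, config) {
  stopifnot(inherits(start, "mito_arrangement"),
            inherits(config, "dmnl_config"))
  if (isTRUE(start$is_dimer)) stop("start must be monomeric")
  log <- character()
  if (config$d_timing == "before") {
    start <- translocate(start, "D", config$d_pre_target)
    log <- c(log, sprintf("translocate-D (before DMNL): to between %s and %s",
                          config$d_pre_target[1], config$d_pre_target[2]))
  }
  dimer <- dimerize(start)
  log <- c(log, "dimerize: head-to-tail dimer, 2 CRs")
  res <- nonrandom_loss(dimer, config)
  log <- c(log, res$event_log)
  if (!is_adjacent(res$final, "D", config$d_target)) {
    res$final <- translocate(res$final, "D", config$d_target)
    res$with_spacers <- translocate(res$with_spacers, "D", config$d_target)
    log <- c(log, sprintf("translocate-D (after DMNL): to between %s and %s",
                          config$d_target[1], config$d_target[2]))
  }
  if (config$v_shuffle) {
    res$final <- shuffle_v(res$final)
    res$with_spacers <- shuffle_v(res$with_spacers)
    log <- c(log, "shuffle-V: 12S-V-16S -> 16S-V-L1")
  }
  res$event_log <- log
  res$config <- config
  # refresh the degeneration record against the final arrangement
  res$degenerated <- refresh_loci(res)
  res
}

# locate each spacer's surviving neighbors in the final (post-move) order
refresh_loci <- function(res) {
  f <- res$with_spacers$features
  n <- nrow(f)
  sp <- which(f$category == "spacer")
  non_sp <- which(f$category != "spacer")
  nearest <- function(i, dir) {
    d <- if (dir > 0) (non_sp - i) %% n else (i - non_sp) %% n
    non_sp[which.min(replace(d, d == 0, n + 1L))]
  }
  data.frame(
    source = sub("'$", "", f$provenance[sp]),
    copy = ifelse(grepl("'$", f$provenance[sp]), "prime", "plain"),
    left = f$name[vapply(sp, nearest, integer(1), dir = -1L)],
    right = f$name[vapply(sp, nearest, integer(1), dir = 1L)],
    stringsAsFactors = FALSE)
}

#' @export
print.dmnl_result <- function(x, ...) {
  cat("DMNL result\n")
  if (!is.null(x$config)) {
    cat(sprintf("  variant: Type %s\n", x$config$type_label))
  }
  cat(sprintf("  degenerated features: %d\n", nrow(x$degenerated)))
  cat("  event log:\n")
  cat(paste0("    ", x$event_log, collapse = "\n"), "\n")
  cat("  final order:\n")
  print(x$final)
  invisible(x)
}
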