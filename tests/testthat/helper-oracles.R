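# Independent brute-force oracles.  These deliberately re-derive expected
# values by exhaustive enumeration with their own code paths; they are slow
# and only run on tiny inputs.

# exhaustive stem-loop search: every (start, stem, loop) framing, same
# qualification rules as the detector (terminal pairs real, internal
# mismatches bounded), best = max stem, then min mismatches, then leftmost
brute_hairpin <- function(seq, min_stem = 8, max_stem = 16, min_loop = 3,
                          max_loop = 15, max_mismatch = 1, allow_gu = TRUE) {
  s <- toupper(seq)
  n <- nchar(s)
  pairs_ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "GC", "CG") ||
      (allow_gu && p %in% c("GT", "TG"))
  }
  best <- NULL
  for (i in 1:n) {
    for (k in min_stem:max_stem) {
      for (loop in min_loop:max_loop) {
        last <- i + 2 * k + loop - 1
        if (last > n) next
        ok <- logical(k)
        for (t in 1:k) {
          ok[t] <- pairs_ok(substr(s, i + t - 1, i + t - 1),
                            substr(s, last - t + 1, last - t + 1))
        }
        if (!ok[1] || !ok[k]) next
        mm <- sum(!ok)
        if (mm > max_mismatch) next
        cand <- list(start = i - 1, end = last, stem = k, loop = loop,
                     mm = mm)
        if (is.null(best) ||
            cand$stem > best$stem ||
            (cand$stem == best$stem && cand$mm < best$mm)) {
          best <- cand
        }
      }
    }
  }
  best
}

# exhaustive exact tandem-array search by block comparison: largest array
# (span, then smallest period) with >= min_copies total copies
brute_best_tandem <- function(seq, min_period = 10, min_copies = 3) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- NULL
  for (p in min_period:(n %/% 2)) {
    for (i in 1:(n - 2 * p + 1)) {
      motif <- substr(s, i, i + p - 1)
      j <- i + p
      copies <- 1
      while (j + p - 1 <= n && substr(s, j, j + p - 1) == motif) {
        copies <- copies + 1
        j <- j + p
      }
      # partial final copy
      rem <- 0
      while (j + rem <= n &&
             substr(s, j + rem, j + rem) == substr(motif, rem + 1, rem + 1)) {
        rem <- rem + 1
      }
      total <- copies + rem / p
      if (total < min_copies) next
      span <- copies * p + rem
      cand <- list(period = p, copies = total, start = i - 1, span = span)
      if (is.null(best) || span > best$span ||
          (span == best$span && p < best$period)) {
        best <- cand
      }
    }
  }
  best
}

# hand enumeration of DMNL spacer loci from first principles: walk the
# canonical order, mark which copies survive under the default promoter
# loss, and collect runs of degenerated features between survivors
oracle_spacer_loci <- function(type) {
  canon <- c("F", "12S", "V", "16S", "L1", "ND1", "I", "Q", "M", "ND2",
             "W", "A", "N", "OL", "C", "Y", "COI", "S1", "D", "COII", "K",
             "ATP8", "ATP6", "COIII", "G", "ND3", "R", "ND4L", "ND4", "H",
             "S2", "L2", "ND5", "ND6", "E", "CytB", "T", "P", "CR")
  lgenes <- c("Q", "A", "N", "C", "Y", "S1", "ND6", "E", "P")
  h <- setdiff(canon, c(lgenes, "OL", "CR"))
  # copy 1 keeps its H genes, N and OL; copy 2 keeps its other L genes;
  # CR survival per type
  surv1 <- canon %in% c(h, "N", "OL") |
    (canon == "CR" & type %in% c("I", "II", "III"))
  surv2 <- canon %in% setdiff(lgenes, "N") |
    (canon == "CR" & type %in% c("III", "IV"))
  nm1 <- canon
  nm2 <- canon
  if (type == "III") {
    nm1[canon == "CR"] <- "CR1"
    nm2[canon == "CR"] <- "CR2"
  }
  nm <- c(nm1, nm2)
  surv <- c(surv1, surv2)
  src <- c(canon, canon)
  n <- length(nm)
  # collect (left, right, sources) by circular walk starting from the first
  # surviving feature
  first <- which(surv)[1]
  idx <- c(first:n, seq_len(first - 1))
  walk_nm <- nm[idx]
  walk_surv <- surv[idx]
  walk_src <- src[idx]
  surv_seq <- walk_nm[walk_surv]
  loci <- list()
  pend <- character()
  prev <- tail(surv_seq, 1)
  for (i in seq_along(walk_nm)) {
    if (walk_surv[i]) {
      if (length(pend)) {
        loci[[length(loci) + 1]] <- list(left = prev, right = walk_nm[i],
                                         sources = pend)
      }
      pend <- character()
      prev <- walk_nm[i]
    } else {
      pend <- c(pend, walk_src[i])
    }
  }
  if (length(pend)) {
    loci[[length(loci) + 1]] <- list(left = prev, right = surv_seq[1],
                                     sources = pend)
  }
  # apply the D move to the locus list: D leaves its canonical position
  # (the run ending at D now ends at COII) and re-inserts immediately left
  # of its new right neighbor (ND6 inside the cluster, or the CR after T
  # for Type I)
  for (j in seq_along(loci)) {
    l <- loci[[j]]$left
    r <- loci[[j]]$right
    if (r == "D") loci[[j]]$right <- "COII"
    if (l == "D") loci[[j]]$left <- "COI"
    if (type != "I" && r == "ND6") loci[[j]]$right <- "D"
    if (type == "I" && l == "T" && r == "CR") loci[[j]]$right <- "D"
  }
  loci
}
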