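# Hairpin search, O_L mode cascade, motifs, tandem repeats, TAS core.

test_that("find_hairpin detects constructed stem-loops", {
  # perfect 10 bp inverted repeat around a 5 nt loop
  stem <- "GGATCCGGAT"
  s <- paste0("TTTTT", stem, "AACGA", rc(stem), "TTTTT")
  h <- find_hairpin(s)
  expect_equal(h$stem_len_bp, 10L)
  expect_equal(h$mismatches, 0L)
  expect_equal(c(h$start, h$end), c(5L, 30L))
  # too short
  expect_null(find_hairpin("ACGTACG"))
  expect_error(find_hairpin("ACGTNNN"), "non-nucleotide")
  # one internal mismatch
  stem1 <- "GGATCCGGAT"
  stem2 <- rc(stem1)
  substr(stem2, 5, 5) <- "A"   # breaks one internal pair
  s2 <- paste0("TTTTT", stem1, "AACGA", stem2, "TTTTT")
  h2 <- find_hairpin(s2)
  expect_equal(h2$stem_len_bp, 10L)
  expect_equal(h2$mismatches, 1L)
})

test_that("find_hairpin agrees with the brute-force oracle", {
  set.seed(99)
  hits <- 0L
  for (rep in 1:30) {
    s <- random_dna(sample(30:60, 1))
    mine <- find_hairpin(s)
    ref <- brute_hairpin(s)
    if (is.null(ref)) {
      expect_null(mine)
    } else {
      hits <- hits + 1L
      expect_equal(mine$stem_len_bp, ref$stem)
      expect_equal(mine$mismatches, ref$mm)
    }
  }
  expect_gt(hits, 0L)   # the sample exercised both outcomes
})

test_that("detect_ol reports the planted formation mode and site", {
  modes <- c("spacer_only", "spacer_plus_trnaN_3prime", "trnaN_middle")
  for (mode in modes) {
    for (seed in c(101, 102)) {
      p <- synth_params(seed = seed, ol_mode = mode)
      g <- synth_sequence(bothid_fixture("C.az"), p)
      h <- detect_ol(g)
      expect_equal(h$mode, mode, info = paste(mode, seed))
      if (mode == "spacer_plus_trnaN_3prime") {
        expect_equal(h$trnaN_bases_used, 4L)
        expect_equal(h$motif5, "GGTGG")
        expect_equal(h$motif3, "TAGA")
      }
      if (mode == "trnaN_middle") {
        expect_equal(h$trnaN_bases_used, 26L)
      }
    }
  }
  # borrowed-base count follows the generator's setting
  p5 <- synth_params(seed = 103, ol_mode = "spacer_plus_trnaN_3prime",
                     trnaN_bases = 5L)
  expect_equal(detect_ol(synth_sequence(bothid_fixture("G.p"), p5))$
                 trnaN_bases_used, 5L)
})

test_that("scan_motifs annotates the conserved flanks", {
  stem <- "GGATCCGGAT"
  core <- paste0(stem, "AACGA", rc(stem))
  s <- paste0("GGTGGAA", core, "CCTAGA")
  h <- scan_motifs(s, find_hairpin(s))
  expect_equal(h$motif5, "GGTGG")
  expect_equal(h$motif3, "TAGA")
  # variant 5' motif
  s2 <- paste0("GGGGGAA", core, "CCTAGA")
  expect_equal(scan_motifs(s2, find_hairpin(s2))$motif5, "GGGGG")
  # no flanking motifs: hairpin still reported, motifs absent
  s3 <- paste0("TTTTTTT", core, "TTTTTTT")
  h3 <- scan_motifs(s3, find_hairpin(s3))
  expect_true(is.na(h3$motif5) && is.na(h3$motif3))
  expect_equal(h3$stem_len_bp, 10L)
})

test_that("tandem repeats are recovered exactly on constructed arrays", {
  set.seed(5)
  motif <- "ACGTTGCAGGTCAGTTACCGAT"   # 22-mer
  # flank boundary bases must not continue the array pattern
  flank1 <- paste0(random_dna(59), "G")  # motif ends in T
  flank2 <- paste0("C", random_dna(59))  # motif starts with A
  s <- paste0(flank1, strrep(motif, 35), flank2)
  rep_ <- find_tandem_repeats(s)
  top <- rep_[1, ]
  ref <- brute_best_tandem(s)
  expect_equal(top$period_bp, 22L)
  expect_equal(top$copies, 35.0)
  expect_equal(top$period_bp, ref$period)
  expect_equal(top$copies, round(ref$copies, 1))
  expect_equal(top$start, ref$start)
  expect_equal(top$motif, motif)

  # periods 10-30, copies 3-40 recovered exactly
  for (case in list(c(10, 3), c(15, 12), c(30, 40))) {
    m <- paste0("T", random_dna(case[1] - 2), "A")  # guarded against C/G flanks
    arr <- find_tandem_repeats(paste0("CCCCC", strrep(m, case[2]), "GGGGG"),
                               min_period = case[1] - 2)
    expect_equal(arr$period_bp[1], case[1])
    expect_equal(arr$copies[1], case[2])
  }

  # seeded random 500-mer: nothing at period >= 10 with >= 3 copies,
  # confirmed by brute force
  s0 <- random_dna(500, seed = 1234)
  expect_equal(nrow(find_tandem_repeats(s0)), 0L)
  expect_null(brute_best_tandem(s0))

  # short-period convenience case
  ac <- find_tandem_repeats("ACACACAC", min_period = 2)
  expect_equal(ac$period_bp[1], 2L)
  expect_equal(ac$copies[1], 4.0)
})

test_that("TAS core scan honors the single-wildcard pattern", {
  expect_equal(scan_tas("ACATCTGTA")$pos, 0L)
  t2 <- scan_tas("ACATTTGTA")
  expect_equal(t2$pos, 0L)
  expect_equal(t2$middle, "T")
  expect_equal(nrow(scan_tas("ACATTTTTT")), 0L)
  hits <- scan_tas("GGACATCTGTAGGACATGTGTAGG")
  expect_equal(hits$pos, c(2L, 13L))
  expect_equal(hits$middle, c("C", "G"))
})

test_that("synthetic control regions carry TAS and the 3' repeat array", {
  p <- synth_params(seed = 41)
  g <- synth_sequence(bothid_fixture("G.p"), p)
  for (crname in c("CR1", "CR2")) {
    crf <- g$features[g$features$name == crname, ]
    crs <- substr(g$seq, crf$start + 1L, crf$end)
    expect_equal(scan_tas(crs)$pos[1], 20L)   # planted at tas_offset
    arr <- find_tandem_repeats(crs)
    expect_equal(arr$period_bp[1], 22L)
    expect_equal(arr$copies[1], 35.0)
  }
})
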