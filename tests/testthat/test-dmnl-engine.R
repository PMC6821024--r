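# DMNL engine: dimerization, transcription units, non-random loss, full runs.

test_that("dimerize doubles the genome with prime-tagged second copy", {
  canon <- canonical_teleost_order()
  dimer <- dimerize(canon)
  expect_true(dimer$is_dimer)
  g <- gene_order(dimer)
  expect_equal(nrow(g), 74L)
  expect_equal(sum(dimer$features$category == "control"), 2L)
  expect_equal(sum(dimer$features$category == "origin"), 2L)
  # each gene exactly once per copy tag
  expect_true(all(table(g$name, g$copy) == 1L))
  expect_error(dimerize(dimer), "already a dimer")
  # a pre-translocated D is duplicated at the translocated locus
  pre <- translocate(canon, "D", c("T", "P"))
  d2 <- dimerize(pre)$features
  di <- which(d2$name == "D")
  expect_equal(d2$name[di - 1L], c("T", "T"))
})

test_that("transcription units cover the expected gene sets", {
  dimer <- dimerize(canonical_teleost_order())
  # all four promoters functional: every gene transcribed
  units <- transcription_units(dimer, dimer_promoters(dimer))
  covered <- sort(unique(unlist(lapply(units, `[[`, "transcribed"))))
  expect_equal(length(covered), 74L)

  # only HSP'/LSP' functional: L-transcribed set is the prime 9-gene set
  # (before the tRNA-N retention adjustment), H-transcribed the plain copy
  prom <- dimer_promoters(dimer, lost = c("HSP", "LSP"))
  units <- transcription_units(dimer, prom)
  f <- dimer$features
  lsp <- units[[which(vapply(units, `[[`, character(1), "promoter_id") ==
                        "LSP_prime")]]
  expect_setequal(f$name[lsp$transcribed],
                  c("Q", "A", "N", "C", "Y", "S1", "ND6", "E", "P"))
  expect_true(all(f$copy[lsp$transcribed] == "prime"))
  hsp <- units[[which(vapply(units, `[[`, character(1), "promoter_id") ==
                        "HSP_prime")]]
  expect_true(all(f$copy[hsp$transcribed] == "plain"))
  expect_true(all(c("F", "12S", "V", "ND5", "CytB", "T") %in%
                    f$name[hsp$transcribed]))
})

test_that("non-random loss retains tRNA-N (not N') and handles CR modes", {
  dimer <- dimerize(canonical_teleost_order())
  res3 <- nonrandom_loss(dimer, dmnl_config("III"))
  # equals the Type III fixture minus the D translocation
  gp_pre <- translocate(bothid_fixture("G.p"), "D", c("COI", "COII"))
  expect_true(arrangements_equal(res3$final, gp_pre))
  # the retained N is the plain copy (adjacent to the surviving COI)
  expect_equal(res3$survivor_copy[["N"]], "plain")
  prov <- res3$with_spacers$features$provenance
  expect_true("N'" %in% prov)    # the transcription-expected copy is lost
  expect_false("N" %in% prov)    # the plain copy is not

  # Type IV: single CR located after P
  res4 <- nonrandom_loss(dimer, dmnl_config("IV"))
  f4 <- res4$final$features
  expect_equal(sum(f4$category == "control"), 1L)
  expect_equal(f4$name[which(f4$name == "CR") - 1L], "P")
})

test_that("run_dmnl reproduces every fixture under its type config", {
  canon <- canonical_teleost_order()
  for (sp in all_species) {
    res <- run_dmnl(canon, fixture_config(sp))
    expect_true(arrangements_equal(res$final, bothid_fixture(sp)),
                info = sp)
  }
  # both timings converge to the same final order
  for (ty in c("I", "II", "III", "IV")) {
    a <- run_dmnl(canon, dmnl_config(ty, d_timing = "after"))$final
    b <- run_dmnl(canon, dmnl_config(ty, d_timing = "before"))$final
    expect_true(arrangements_equal(a, b), info = ty)
  }
})

test_that("DMNL conserves genes, strands and within-cluster order", {
  canon <- canonical_teleost_order()
  cg <- gene_order(canon)
  canonical_strand <- setNames(cg$strand, cg$name)
  h_order <- cg$name[cg$strand == "H"]
  for (ty in c("I", "II", "III", "IV")) {
    for (vs in if (ty == "IV") c(FALSE, TRUE) else FALSE) {
      res <- run_dmnl(canon, dmnl_config(ty, v_shuffle = vs))
      g <- gene_order(res$final)
      # gene conservation: each of the 37 exactly once
      expect_equal(sort(g$name), sort(cg$name))
      # strand preservation (no inversions)
      expect_equal(canonical_strand[g$name], setNames(g$strand, g$name))
      # surviving H genes keep their canonical relative order
      # (up to rotation; D and, with the shuffle, V are the movers)
      keep_h <- setdiff(h_order, c("D", if (vs) "V"))
      obs_h <- g$name[g$name %in% keep_h]
      i0 <- match(obs_h[1], keep_h)
      expect_equal(obs_h, keep_h[((seq_along(keep_h) + i0 - 2L) %%
                                    length(keep_h)) + 1L])
      # the L cluster reads Q,A,C,Y,S1,(D,)ND6,E,P
      run <- longest_l_strand_run(res$final)
      if (ty == "I") {
        expect_equal(run, c("Q", "A", "C", "Y", "S1", "ND6", "E", "P"))
      } else {
        expect_equal(run, c("Q", "A", "C", "Y", "S1"))
      }
    }
  }
})

test_that("degeneration record lists each lost copy between its survivors", {
  res <- run_dmnl(canonical_teleost_order(), dmnl_config("III"))
  d <- res$degenerated
  # 37 + CR + OL per copy, minus 37 surviving genes, one OL, two CRs
  expect_equal(nrow(d), 2L * 39L - 37L - 1L - 2L)
  # the expected tRNA-N' degeneration (prime copy lost, plain retained)
  expect_true(any(d$source == "N" & d$copy == "prime"))
  expect_false(any(d$source == "N" & d$copy == "plain"))
  # S1 (plain) remnant sits between COI and COII after the D move
  s1 <- d[d$source == "S1" & d$copy == "plain", ]
  expect_equal(c(s1$left, s1$right), c("COI", "COII"))
})
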