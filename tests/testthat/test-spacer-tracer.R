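# Spacer-locus prediction, matching against annotated genomes, census.

test_that("predicted loci match an independent hand enumeration", {
  for (ty in c("I", "II", "III", "IV")) {
    pred <- predict_spacer_loci(dmnl_config(ty))
    oracle <- oracle_spacer_loci(ty)
    okey <- sort(vapply(oracle, function(l)
      paste(l$left, l$right, paste(sort(l$sources), collapse = ";")),
      character(1)))
    pkey <- sort(vapply(seq_len(nrow(pred)), function(i)
      paste(pred$left[i], pred$right[i],
            paste(sort(strsplit(pred$candidate_sources[i], ";")[[1]]),
                  collapse = ";")),
      character(1)))
    expect_equal(pkey, okey, info = ty)
  }
})

test_that("well-known loci carry their census ids and sources", {
  pred <- predict_spacer_loci(dmnl_config("III"))
  key <- paste(pred$left, pred$right)
  # the N/O_L-COI spacer (locus 3) descends from the rearranged C and Y
  expect_equal(pred$candidate_sources[key == "OL COI"], "C;Y")
  expect_equal(pred$locus_id[key == "OL COI"], "3")
  # Type I/II: long CR remnant between P and F (locus 12)
  pred2 <- predict_spacer_loci(dmnl_config("II"))
  key2 <- paste(pred2$left, pred2$right)
  expect_equal(pred2$candidate_sources[key2 == "P F"], "CR")
  expect_equal(pred2$locus_id[key2 == "P F"], "12")
  # no locus between two retained canonical neighbors (no false loci)
  expect_false("ND6 E" %in% key)   # ND6-E adjacent and both retained
  expect_false("K ATP8" %in% key)
})

test_that("matching recovers planted remnant lengths exactly", {
  p <- synth_params(seed = 21)
  dimer <- synth_sequence(dimerize(canonical_teleost_order()), p)
  cfg <- dmnl_config("III")
  ev <- evolve_degeneration(dimer, cfg, p)
  m <- match_observed(predict_spacer_loci(cfg), ev)
  gt <- ev$ground_truth$remnants
  want <- aggregate(remnant_len ~ left + right, gt, sum)
  for (i in seq_len(nrow(want))) {
    hit <- m$left == want$left[i] & m$right == want$right[i]
    expect_equal(sum(hit), 1L)
    expected <- if (want$remnant_len[i] >= 2) want$remnant_len[i]
                else NA_integer_
    expect_equal(m$observed_length_bp[hit], expected,
                 info = paste(want$left[i], want$right[i]))
  }
  # true source is always among the candidates of its locus
  for (i in which(gt$remnant_len > 0)) {
    hit <- m$left == gt$left[i] & m$right == gt$right[i]
    expect_true(gt$source[i] %in%
                  strsplit(m$candidate_sources[hit], ";")[[1]])
  }
})

test_that("matching refuses a genome of mismatched type", {
  p <- synth_params(seed = 22)
  dimer <- synth_sequence(dimerize(canonical_teleost_order()), p)
  ev4 <- evolve_degeneration(dimer, dmnl_config("IV"), p)
  expect_error(match_observed(predict_spacer_loci(dmnl_config("III")), ev4),
               "mismatch")
})

test_that("fully disappeared genes leave unmatched loci", {
  p <- synth_params(seed = 23, p_disappear = 1)
  dimer <- synth_sequence(dimerize(canonical_teleost_order()), p)
  cfg <- dmnl_config("III")
  ev <- evolve_degeneration(dimer, cfg, p)
  m <- match_observed(predict_spacer_loci(cfg), ev)
  # all gene remnants vanish; only... none are left (Type III keeps CRs)
  expect_true(all(is.na(m$observed_length_bp)))
})

test_that("the census counts per-species unique spacers", {
  cfg <- dmnl_config("III")
  traced <- list()
  for (seed in 31:32) {
    p <- synth_params(seed = seed)
    dimer <- synth_sequence(dimerize(canonical_teleost_order()), p)
    ev <- evolve_degeneration(dimer, cfg, p)
    traced[[paste0("sp", seed)]] <- match_observed(predict_spacer_loci(cfg),
                                                   ev)
  }
  cen <- spacer_census(traced)
  n1 <- sum(!is.na(traced$sp31$observed_length_bp))
  n2 <- sum(!is.na(traced$sp32$observed_length_bp))
  expect_equal(cen$per_species$n_spacers, c(n1, n2))
  expect_equal(cen$n_unique, n1 + n2)
  # a locus observed in both species appears once with n_species = 2
  shared <- cen$per_locus[cen$per_locus$n_species == 2L, ]
  expect_gt(nrow(shared), 0L)
  expect_false(any(duplicated(paste(cen$per_locus$left,
                                    cen$per_locus$right))))
  # empty case
  cen0 <- spacer_census(list(a = predict_spacer_loci(cfg)))
  expect_equal(cen0$per_species$n_spacers, 0L)
  expect_equal(cen0$n_unique, 0L)
})
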