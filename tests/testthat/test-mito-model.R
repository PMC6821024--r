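# Core data model: canonical order, fixtures, equality, strand counts, I/O.

test_that("canonical teleost order has the expected composition", {
  canon <- canonical_teleost_order()
  g <- gene_order(canon)
  expect_equal(nrow(g), 37L)
  expect_equal(sum(canon$features$category == "control"), 1L)
  expect_equal(sum(canon$features$category == "origin"), 1L)
  expect_equal(unname(strand_counts(canon)), c(28L, 9L))
  expect_setequal(g$name[g$strand == "L"],
                  c("ND6", "Q", "A", "N", "C", "Y", "S1", "E", "P"))
  # O_L between tRNA-N and tRNA-C
  f <- canon$features
  oi <- which(f$category == "origin")
  expect_equal(f$name[c(oi - 1L, oi + 1L)], c("N", "C"))
})

test_that("bothid fixtures encode the published gene orders", {
  # Type III representative: CR1 between T and Q, CR2 between P and F
  gp <- bothid_fixture("G.p")
  nm <- gp$features$name
  expect_equal(nm[match("CR1", nm) + c(-1L, 1L)], c("T", "Q"))
  expect_equal(nm[length(nm)], "CR2")
  expect_equal(nm[match("CR2", nm) - 1L], "P")
  expect_equal(unname(strand_counts(gp)), c(28L, 9L))

  # Type I: D then CR between T and Q
  caz <- bothid_fixture("C.az")$features$name
  ti <- match("T", caz)
  expect_equal(caz[ti + 1:2], c("D", "CR"))

  # A.in: tRNA-V shuffled to between 16S and L1
  ain <- bothid_fixture("A.in")$features$name
  expect_equal(ain[2:5], c("12S", "16S", "V", "L1"))

  # Type III members share one order; all five identical to G.p
  for (sp in c("A.t", "L.g", "L.l", "P.i")) {
    expect_true(arrangements_equal(gp, bothid_fixture(sp)))
  }
  expect_error(bothid_fixture("X.x"), "unknown species code")
})

test_that("arrangements_equal is rotation-invariant and an equivalence", {
  canon <- canonical_teleost_order()
  set.seed(42)
  for (k in sample.int(38, 5)) {
    expect_true(arrangements_equal(canon, rotate_arrangement(canon, k)))
  }
  expect_false(arrangements_equal(canon, bothid_fixture("G.p")))
  # symmetric + transitive across randomly rotated copies
  a <- rotate_arrangement(bothid_fixture("B.my"), 7)
  b <- rotate_arrangement(bothid_fixture("B.my"), 21)
  c_ <- bothid_fixture("B.my")
  expect_true(arrangements_equal(a, a))
  expect_true(arrangements_equal(a, b) && arrangements_equal(b, a))
  expect_true(arrangements_equal(a, b) && arrangements_equal(b, c_) &&
                arrangements_equal(a, c_))
  # monomer vs dimer comparison is refused
  expect_error(arrangements_equal(canon, dimerize(canon)), "dimer")
})

test_that("strand counts ignore non-genes and handle empty input", {
  empty <- arrangement(data.frame(name = character(), strand = character()))
  expect_equal(unname(strand_counts(empty)), c(0L, 0L))
  expect_equal(unname(strand_counts(canonical_teleost_order())), c(28L, 9L))
})

test_that("tabular round-trip preserves arrangements including spacers", {
  canon <- canonical_teleost_order()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_arrangement(canon, path)
  expect_true(arrangements_equal(read_arrangement(path), canon))

  # with a provenance-tagged spacer and explicit lengths
  f <- canon$features
  sp <- data.frame(name = "SPACER", strand = "H", category = "spacer",
                   copy = "plain", provenance = "Q", length_bp = 33L)
  withsp <- arrangement(rbind(f[1:7, ], sp, f[8:nrow(f), ]))
  write_arrangement(withsp, path)
  back <- read_arrangement(path)
  expect_true(arrangements_equal(back, withsp, include_spacers = TRUE))
  bsp <- back$features[back$features$category == "spacer", ]
  expect_equal(bsp$provenance, "Q")
  expect_equal(bsp$length_bp, 33L)
})

test_that("malformed gene-order files are reported with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#circular anchor=F", "F\t+\ttRNA", "XX\t+\ttRNA"), path)
  expect_error(read_arrangement(path), "XX.*line 3|line 3.*XX")
  writeLines(c("F\t+\ttRNA", "D\t+\ttRNA", "D\t+\ttRNA"), path)
  expect_error(read_arrangement(path), "duplicate gene 'D'.*line 3")
  writeLines("F only-one-field", path)
  expect_error(read_arrangement(path), "malformed line 1")
})

test_that("GenBank feature tables map to the controlled vocabulary", {
  gb <- c(
    "LOCUS       TEST 400 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..70",
    '                     /product="tRNA-Phe"',
    "     rRNA            71..160",
    '                     /product="12S ribosomal RNA"',
    "     CDS             161..300",
    '                     /gene="ND1"',
    "     tRNA            complement(301..370)",
    '                     /product="tRNA-Gln"',
    "     D-loop          371..400",
    "ORIGIN",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  a <- read_genbank_arrangement(path)
  expect_equal(a$features$name, c("F", "12S", "ND1", "Q", "CR"))
  expect_equal(a$features$strand, c("H", "H", "H", "L", "H"))
  expect_equal(a$features$length_bp[1], 70L)
})
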