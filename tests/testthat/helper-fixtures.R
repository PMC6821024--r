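# shared helpers for the test suite

all_species <- names(bothid_species_codes())

fixture_config <- function(sp) {
  dmnl_config(bothid_species_codes()[[sp]], v_shuffle = identical(sp, "A.in"))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
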