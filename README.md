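# dmnl

Mitochondrial gene-order rearrangement analysis under the
**Dimer-Mitogenome and Non-Random Loss (DMNL)** model, built around the
genomic-scale rearrangements of bothid flatfish (Pleuronectiformes:
Bothidae) mitogenomes.

## The problem and the model

A typical teleost mitogenome carries 37 genes (13 protein-coding, 2 rRNA,
22 tRNA) plus a control region (CR) and the light-strand replication
origin (O_L); 28 genes sit on the heavy (H) strand and *ND6* plus eight
tRNAs (*Q, A, N, C, Y, S1, E, P*) on the light (L) strand.  Bothid
mitogenomes instead show genes sorted by transcriptional polarity: an
8-gene L-strand cluster *Q-A-C-Y-S1-ND6-E-P* that conspicuously excludes
*tRNA-N*, an H-strand block *F-12S … CytB-T*, and one of four layouts of
the CR(s) and *tRNA-D* (Types I–IV).

The DMNL model explains this in three steps:

1. **Dimerization** — two monomers fuse head-to-tail into a dimer with two
   CRs, each hosting an H- and an L-strand transcription promoter
   (HSP/LSP and HSP′/LSP′).  H-strand transcription terminates at the TAS
   of the next CR; L-strand transcription at the first *tRNA-L1* copy.
2. **Promoter loss** — one CR's promoter pair mutates silent.  Genes no
   longer inside any functional transcription unit become dispensable.
3. **Non-random loss** — each dispensable gene degenerates in place into a
   short intergenic spacer (2–88 bp, or disappears; a degenerate CR leaves
   155–511 bp).  The exception is *tRNA-N*: the copy adjacent to the
   surviving *COI* is retained — not the transcription-covered *N′* —
   because its sequence supports O_L function when the remaining spacer
   cannot fold the O_L stem-loop on its own.

The package implements the model end to end, at the gene-order level
(simulation, type classification, translocation-timing parsimony,
spacer-provenance tracing) and at the sequence level (O_L stem-loop
detection with the three formation modes, TAS-core and tandem-repeat
scans, and a ground-truthed synthetic-genome generator).

## Worked example

```r
library(dmnl)

canon <- canonical_teleost_order()
res <- run_dmnl(canon, dmnl_config("III"))
res$final
#> Circular monomeric mitochondrial arrangement: 40 features (37 genes)
#>   F 12S V 16S L1 ND1 I M ND2 W -N OL COI COII K ATP8 ATP6 COIII G ND3 R
#>   ND4L ND4 H S2 L2 ND5 CytB T CR1 -Q -A -C -Y -S1 D -ND6 -E -P CR2
#>   (linearized at F; '-' marks L-strand genes)

arrangements_equal(res$final, bothid_fixture("G.p"))
#> [1] TRUE

classify_arrangement(bothid_fixture("C.az"))
#> Rearrangement type: I (CRs: 1; tRNA-D outside the cluster)

parsimony_table(c("C.az", "B.my"))
#>   species type before after verdict
#> 1    C.az    I      1     1     tie
#> 2    B.my   II      2     1   after
```

The simulated Type III order reproduces the *Grammatobothus
polyophthalmus* gene order: the H-strand block ends at *tRNA-T*, CR1
separates it from the 9-gene cluster *Q-A-C-Y-S1-D-ND6-E-P*, and CR2
precedes *tRNA-F*.  The parsimony table shows why *tRNA-D* translocation
is inferred to postdate the loss step in Types II–IV (one move after
vs. two straddling it) while Type I is a tie (one move either way).

Sequence-level work runs off the generator:

```r
p <- synth_params(seed = 1)
g <- synth_sequence(bothid_fixture("G.p"), p)
detect_ol(g)
#> Stem-loop at [5174,5195): stem 8 bp (0 mismatch, 0 G.U), loop 5 nt
#>   formation mode: spacer_only (tRNA-N bases used: 0)
#>   flanking motifs: 5' GGTGG, 3' TAGA
#>   ((((((((.....))))))))
```

A thin command-line front end over the same functions ships in
`inst/scripts/dmnl-cli.R` (subcommands `simulate`, `classify`,
`parsimony`, `trace`, `find-ol`, `scan-cr`, `generate`).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the headline quantities of the analysis — the gene and H-strand
counts of the Type III simulation, the length of the L-strand cluster in
the Type I simulation, and the number of gene orders whose scenario
search strictly favors post-loss *tRNA-D* translocation — and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Wet-lab concerns (annotation from raw sequence, BLAST/tRNAscan-SE,
thermodynamic folding) are out of scope; the hairpin detector is a
combinatorial base-pairing heuristic, and gene orders for the 13 bothid
species are bundled as order-level fixtures.  See the vignette
(`vignettes/dmnl-model.Rmd`) for the model's assumptions, parameter
choices and limitations.
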