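---
title: "The DMNL model: simulating and testing dimer-mediated mitochondrial gene rearrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DMNL model: simulating and testing dimer-mediated mitochondrial gene rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnl)
```

## The mechanism

Most fish mitogenomes share one gene order: 37 genes, a control region
(CR) and the light-strand replication origin (O_L) between *tRNA-N* and
*tRNA-C* of the WANCY tRNA cluster.  Bothid flatfishes instead carry
genomic-scale rearrangements in which genes are grouped by
transcriptional polarity.  The Dimer-Mitogenome and Non-Random Loss
(DMNL) mechanism accounts for this as follows.

Two monomers fuse head-to-tail into a circular dimer with two CRs.  Each
CR hosts a heavy-strand and a light-strand promoter (HSP/LSP in one copy,
HSP′/LSP′ in the other).  An H-strand transcription unit runs from its CR
forward to the termination-associated sequence (TAS) of the next CR; an
L-strand unit runs backward to the first *tRNA-L1* copy.  When one CR's
promoter pair loses function by mutation, the genes covered only by the
dead promoters stop being transcribed, and — mitogenomes being compact —
degenerate.  What survives is one copy of every gene: the H-strand genes
of one monomer copy and the L-strand genes of the other, which are
necessarily contiguous blocks.  That single loss event therefore produces
the observed polarity sorting, including the 8-gene L-strand cluster
*Q-A-C-Y-S1-ND6-E-P*.

Two wrinkles complete the picture:

* **tRNA-N retention.**  Transcription-unit membership predicts the prime
  copy *N′* survives (it sits in the surviving L-strand unit), but the
  observed genomes retain the *other* copy, the one immediately upstream
  of the surviving *COI*.  The model's reading: O_L function.  After
  *tRNA-C* and *tRNA-Y* leave the WANCY neighborhood, the remaining
  N–COI spacer may be too short to fold the O_L stem-loop, and tRNA-N's
  own sequence takes part in (or substitutes for) the structure.  The
  engine implements retention positionally — the N copy adjacent to the
  surviving COI is retained — precisely because the transcription-based
  rule would pick the wrong copy; the structural rationale lives in the
  sequence-feature layer.
* **Control-region bookkeeping** differs by rearrangement type: Types
  I/II keep only the CR between *tRNA-T* and the cluster, Type III keeps
  both (CR1 and CR2), Type IV wholly loses the first CR and keeps the one
  after *tRNA-P*.  Positionally, the single CR of Types I/II is the CR of
  the copy whose promoters died; which physical copy survives is not
  observable from an untagged genome, so the engine simply encodes the
  bookkeeping that reproduces the observed orders (`cr_mode`).

The four rearrangement types differ in that bookkeeping, in where
*tRNA-D* ends up (outside the cluster between T and the CR in Type I,
inside it between *S1* and *ND6* in Types II–IV), and in the *tRNA-V*
shuffle private to one Type IV genome.

## Translocation timing as a parsimony question

*tRNA-D* is an H-strand gene, so after the loss step it sits between
*COI* and *COII* (its canonical neighbor *S1* having degenerated).  Did
its translocation happen before or after the DMNL process?
`scenario_search()` counts the minimal number of single-gene D moves each
timing needs to reach an observed order; dimerization, promoter loss,
degeneration and the V shuffle are not counted, matching how the steps
are tallied in the underlying analysis.  The before-timing must spend one
move in the monomer; because the surviving D comes from the copy whose
L-strand neighbors all degenerate, no single pre-placement can land D
inside the prime-copy cluster, so Types II–IV need a second, post-loss
move (2 vs 1: verdict "after").  In Type I the target lies between T and
the CR, which a single pre-move *can* achieve (1 vs 1: "tie").  Across
the 13 bundled gene orders this yields 10 "after" and 3 "tie".

The search is breadth-first over insertion loci with deduplication, which
terminates quickly because composing two D moves equals one; minimality
is cross-checked in the tests against a brute-force enumeration.

## Spacer tracing

Degeneration-in-place makes a sharp prediction: every intergenic spacer
of a rearranged genome lies between two specific surviving neighbors and
descends from specific genes.  `predict_spacer_loci()` derives those loci
from the engine; consecutive degenerated genes between the same survivors
merge into one locus whose candidate list holds all of them — ambiguity
is represented, never resolved by guessing.  `match_observed()` fills in
observed gap lengths (threshold 2 bp, the shortest spacer class
reported), and `spacer_census()` counts per-species "unique spacers",
excluding adjacencies that also gap in non-rearranged flatfishes (the
12S/16S/V/L1 region, the H–S2 double-A, and three canonical loci; see
`dmnl_unrelated_loci()`).  Locus ids follow the published census
numbering where the text pins it down (locus 3 = the N/O_L–COI spacer;
locus 12 = the long 155–511 bp degenerated-CR remnant between P and F;
6′/10′ the loci split by the translocated D); the remaining assignments
are positional and approximate, and unmapped loci get fresh `x<k>`
labels.

## Sequence-feature detectors

`find_hairpin()` scores stem-loops combinatorially — longest stem, then
fewest mismatches, then leftmost — with Watson–Crick plus optional G·U
pairs, stem ≥ 8 bp (capped at 16; published O_L stems are well under
this), loop 3–15 nt, at most one internal mismatch, and real pairs at
both stem ends so "stem length" is well defined.  No free energies: the
published structures are short canonical stems, and a combinatorial rule
can be verified exactly against a brute-force oracle (the tests do).

`detect_ol()` applies the three formation modes in a fixed cascade that
mirrors the biology: the intergenic region downstream of *tRNA-N* alone
(long spacers, 40–55 bp); then extended by 3, 4, 5 bases from tRNA-N's
spacer-adjacent 3′ end; then a centered 26 nt window inside tRNA-N (the
short-spacer, 7–14 bp case).  The first qualifying hairpin wins.  The
search region ends at the next *gene* downstream of N — tRNA-C in the
ancestral order, COI in rearranged ones — so the same detector serves
both.  Conserved flanking motifs (5′ GGTGG/GGGGG/GCCGG, 3′ TAGA) are
annotated within an 8 nt window.  `scan_tas()` matches the TAS core
ACAT-n-TGTA, and `find_tandem_repeats()` finds arrays by period
autocorrelation, reporting the primitive period on ties.

## The synthetic world

`synth_params()` states the emulated conditions once: tRNAs 65–75 bp,
protein/rRNA lengths from a canonical table (monomers land at ~16–17 kb),
CRs of 900 bp with the TAS core at offset 20 and 35 copies of a 22 bp
motif at the 3′ end, remnants uniform on 2–88 bp with a 15% chance of
complete disappearance, degenerate CRs leaving 155–511 bp, and a planted
O_L hairpin with stem 8/loop 5 and the GGTGG…TAGA flanks.  Values the
underlying analysis states are used as stated; the rest (gene-length
table, 45% GC, the disappearance probability, the TAS offset) are
one-time choices of plausible magnitudes, made here and not revisited.

Design notes worth knowing:

* **Ground truth is true by construction.**  The planted hairpin is
  framed by non-pairing guard bases (so the detector sees exactly the
  planted stem), and the generator rejection-samples its random content
  until its own detector reproduces the planted mode, borrowed-base count
  and site.  Likewise the repeat array's flanks are guarded against
  partial-copy extension.  This is what makes "100% recovery on
  constructed cases" a meaningful check of the detector rather than a
  statement about random sequence.
* **Remnants are slices of their sources**, so provenance is in principle
  sequence-detectable; tracing nevertheless uses only position, as the
  order-level model does.
* **Determinism**: every random choice flows from the mandatory seed
  (degeneration uses seed + 1 so a dimer and its evolution don't share a
  stream), and generation restores the caller's RNG state.

What a green test does **not** establish: synthetic genes are random
sequence (no codon structure, no tRNA cloverleaves), no substitution
process runs over time, and spacer homology decays in no realistic way —
so sequence-similarity-based provenance claims are untested, and
detector performance on real genomes with diverged motifs is outside
what the generator can certify.

## Numerical and degenerate-input choices

Equality of circular orders is rotation-invariant, ignores spacers by
default, and reads any of CR/CR1/CR2 as "a control region"; arrangements
are canonically rotated to *tRNA-F* for stable serialization.
Classification refuses genomes with missing genes and reports
non-matching cluster permutations as `unclassified` rather than guessing
a nearest type.  `translocate()` validates the target adjacency on the
arrangement with the moved gene removed (so a move to the current locus
is a clean no-op) and inserts immediately before the right neighbor,
which keeps a translocated D adjacent to ND6 and leaves merged remnant
runs on the S1 side.  Tandem-repeat copy numbers are reported to one
decimal; fractional trailing copies are counted.  An empty arrangement
has strand counts (0, 0); an unreachable parsimony timing reports
`Inf` events and verdict `unresolved`.

## Limitations

Promoter loss is an instantaneous switch (no mutational dynamics), the
engine models no replication or transcript processing, and only the
single-gene move model is implemented — no DCJ or inversion distances, no
probabilistic or phylogenetic type assignment.  The bundled gene orders
are order-level encodings; base-level coordinates exist only for
synthetic (or user-supplied GenBank) records, so real-data spacer
censuses require the user to supply annotated genomes.
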