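---
title: "Designing CNO-responsive GPCR chimeras: methods and modeling choices"
author: "gpcrchimera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CNO-responsive GPCR chimeras: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrchimera)
```

## The problem

A G protein-coupled receptor (GPCR) separates cleanly into ligand-facing
parts — the N-terminus, the seven transmembrane helices (TM1–7) and the
three extracellular loops (ECL1–3) — and the intracellular parts that hand
the signal on: the three intracellular loops (ICL1–3) and the C-terminus.
A DREADD (Designer Receptor Exclusively Activated by Designer Drugs) is an
engineered muscarinic receptor that ignores acetylcholine and responds to
the inert drug clozapine-N-oxide (CNO). Grafting the intracellular
(signaling) domains of a GPCR-of-interest onto a DREADD scaffold yields a
chimera that binds CNO but signals like the receptor of interest — a
general route to drug-controlled activation of pathways whose natural
ligand is unknown, unavailable, or non-selective.

This package implements the in-silico half of that program:

1. **Domain identification** — annotate any GPCR by projecting a
   reference (rhodopsin-anchored) domain annotation through a protein
   alignment (`align_pairwise()`, `ingest_msa()`, `project_domains()`).
2. **Topology verification** — cross-check the alignment-derived
   annotation against hydropathy-predicted transmembrane helices
   (`predict_tm()`, `check_flanking()`).
3. **Construct assembly** — swap signaling domains, prepend the
   engineered N-terminus, splice the coding DNA from the parents' native
   codons, and add cloning flanks (`assemble_protein()`,
   `assemble_cds()`, `add_restriction_flanks()`).
4. **Candidate selection** — the cell-type specificity statistic and its
   Wilcoxon significance for grouped expression matrices
   (`specificity_analysis()`), used to find receptors enriched in a target
   cell population such as microglia.
5. **Assay normalization** — the standard formulas for baseline/vehicle
   luminescence normalization, dual-reporter fold changes, ddCq and
   lentiviral titration (`baseline_fold_change()`, `ddcq_fold_change()`,
   `lentiviral_titer()`, ...).

## Coordinates and data model

All coordinates are 0-based half-open internally; every human-facing
serialization (GenBank, TSV reports, TM tables) is 1-based inclusive, with
the conversion applied exactly once at the I/O boundary. Sequence records
are validated at construction: proteins over the 20 canonical residues
plus `X`, CDS records over `ACGT` with length divisible by 3 and stop
codons checked. Non-canonical residues are rejected rather than remapped,
because a synthesized construct must carry an exact sequence.

## Domain projection

The reference annotation must tile its protein with the full 15-segment
architecture. For a target aligned to the reference, every reference
segment boundary is mapped through alignment columns: the projected
boundary for reference residue *a* is the number of target residues in
columns strictly before *a*'s column. Equivalently, each target residue
inherits the segment label of the reference residue in its column, and a
residue sitting in a reference-gap column (an insertion) inherits the
label of the nearest *preceding* reference residue. Consequences:

* insertions enlarge the segment they interrupt;
* insertions at a boundary extend the earlier segment (the tie-break that
  guarantees disjointness — the reference does not say how to break this
  tie, so the package fixes one rule and tests it);
* target residues before the first or after the last aligned reference
  residue extend the N- and C-terminus respectively;
* a segment whose reference residues are all deleted in the target
  collapses and is dropped with a warning rather than fabricated.

The test suite checks this implementation against an independent
per-column label-transfer oracle on 200 randomized alignments, and checks
that self-projection is the identity.

Pairwise alignment is Needleman–Wunsch with affine gaps (BLOSUM62, gap
open 10, extend 0.5), delegated to `Biostrings::pairwiseAlignment`, whose
traceback is deterministic. When a pre-computed multiple alignment of the
whole receptor panel is available (e.g. MUSCLE output), `ingest_msa()`
uses it instead — projection then builds the panel-wide signaling-domain
library from a single shared alignment.

## Transmembrane topology as a verification gate

`predict_tm()` is a deliberately simple, fully deterministic hydropathy
predictor standing in for a dedicated HMM tool: mean Kyte–Doolittle
hydropathy over a sliding window (default 19 residues, threshold 1.6,
minimum helix 15, merge gap < 3). Maximal runs of above-threshold window
centers are extended to the window edges. These are standard
Kyte–Doolittle parameters; all are arguments.

`check_flanking()` turns a qualitative expectation — predicted helices
should tightly flank the alignment-identified ICLs and C-termini — into a
quantitative gate. Each annotated TM segment is matched to the
predicted helix that overlaps it most; ICL*k* is flanked upstream by the
helix matched to TM(2k−1) and downstream by TM(2k), the C-terminus
upstream by TM7. Verdicts: *seamless* (gaps ≤ 0 residues),
*minor-deviation* (≤ 5, tolerating minor deviations),
*fail* otherwise. If the required neighbor TM has **no** overlapping
predicted helix the side is reported MISSING and the verdict is *fail* —
this captures the known failure mode of a receptor whose seventh helix a
predictor cannot call with confidence (as happens for GPR109A): its C-terminus fails
with upstream MISSING, rather than being silently matched to TM6 far away.
Verdicts are monotone in the tolerances. The design pipeline fails closed
on any *fail* verdict unless `force = TRUE`.

## Chimera assembly

`assemble_protein()` walks the donor's tiling annotation in order and
replaces each segment in the swap set with the acceptor's corresponding
segment; full swaps (ICL1–3 + C-term) give high-fidelity chimeras, and
partial swaps (e.g. ICL2 + ICL3 only) express earlier chimera designs of
the rM3Ds type. The engineered N-terminus — initiator Met, hemagglutinin
signal peptide `KTIIALSYIFCLVFA`, VSV-G epitope `YTDIEMNRLGK`, `DSL`
linker — is prepended, and the donor's own initiator Met is dropped so
translation cannot initiate downstream of the tag (the DNA-level
counterpart removes the donor's ATG). The signal peptide sequence carries
no Met of its own, yet an ORF must start with ATG; the package's default
is to prepend one (`include_initiator_met = TRUE`), a documented choice at a point where
synthesis practice varies.

`assemble_cds()` splices the DNA: receptor segments keep the native codons
of their parent CDS (cut at 3× the protein coordinates, which
`map_protein_segments_to_cds()` validates by exact translation), while tag
segments — which have no natural CDS — are back-translated with the
most-frequent-human-codon table. One stop codon (TAA by default) is
appended. The defining postcondition, translation of the ORF equals the
chimera protein, is asserted inside the constructor and again in every
test.

`add_restriction_flanks()` adds the cloning sites (EcoRI `GAATTC` or NotI
`GCGGCCGC` upstream, BamHI `GGATCC` downstream) and enforces uniqueness:
each chosen site must occur exactly once in the final construct. An
occurrence inside the ORF is removed by exhaustive synonymous recoding of
the codons it overlaps (all combinations, deterministic order, rejecting
any that alters the translation or creates a new site). A site that
cannot be recoded raises a design error listing the position. With the
standard genetic code, every frame of the three real recognition sites
overlaps at least one degenerate codon, so a genuinely unresolvable case
requires a site tiled entirely by single-codon residues (Met/Trp); the
error branch is exercised with such a synthetic site in the tests.

## Specificity statistic

Replicate expression columns are collapsed to per-group means ("Mean
Data"). For a selected combination *sc* of groups and a disjoint
non-selected combination *n-sc*, the specificity ratio of a gene is

> sr = min(sc row) / max(n-sc row),

so sr > 1 holds exactly when every selected group exceeds every
non-selected group; an all-zero n-sc row yields an undefined/infinite
flag, never an exception. Significance uses the Wilcoxon rank-sum test:
exact by full enumeration of all group assignments (with midranks for
ties) up to a combined n of 12 — appropriate at triplicate scale, where
the normal approximation is unreliable — and tie-corrected normal
approximation above. The default sidedness here
is two-sided (a conservative choice), with `"greater"` available for enrichment
screens. Heatmap rows are normalized to their row maximum. sr is
invariant under global rescaling and p under strictly monotone
transforms; both invariances are property-tested.

## Synthetic fixtures: what they emulate and what they do not

`make_toy_gpcr()` builds N-term + 7 alternating TM/loop blocks + C-term
(TM 21 residues, loops 15, N-term 25, C-term 40 by default, initiator
Met) with exact ground-truth annotations. TM blocks are drawn from
{A, M} and loops from {S, G}. The alphabets are a deliberate calibration,
chosen analytically from the Kyte–Doolittle values before any test was
run: with TM residues at hydropathy 1.8–1.9 and loop residues at −0.4 to
−0.8, a 19-residue window crosses the 1.6 threshold only once it contains
17–18 TM residues, which bounds the predicted boundary error at ±2
residues for *every* random draw. Strongly hydrophobic TM alphabets
(Leu/Ile-rich, as in real receptors) would make detection easier but blur
the boundaries by ~5–7 residues under the same windowing rule, making the
planted annotation useless as a boundary ground truth. The price of the
calibration is realism: these toys have idealized block architecture, no
amphipathic helices, no re-entrant loops, and compositions unlike real
membrane proteins. Passing the recovery tests therefore demonstrates the
correctness of the windowing/flanking machinery, not predictive accuracy
on real sequences — for real work, ingest the output of a dedicated
topology predictor via `ingest_tm_table()`.

`make_expression_matrix()` emulates the *structure* of a cell-type
expression study — 8 cell groups in triplicate, 200 genes, lognormal
per-gene baselines (meanlog log 100, sdlog 1), lognormal replicate noise
σ = 0.3, and 10 planted genes multiplied by fold 4 in the microglia
group. Fold 4 and σ = 0.3 make planted effects recoverable at triplicate
scale, which is what the recovery tests require; they are fixture
parameters, not claims about any real dataset's effect sizes, and the
generator does not emulate microarray intensity distributions,
normalization artifacts, or correlated genes.

All generators are deterministic per seed and restore the caller's RNG
state.

## Problem sizes and numerical choices

The shipped checks use 200 randomized alignments for the projection
oracle, 50 fixture seeds for topology recovery, 100 simulations for
enrichment recovery, and exhaustive enumeration (20 assignments) for the
small Wilcoxon example — sizes at which every property is checked exactly
while the whole suite runs in well under a minute. Stop codon TAA,
most-frequent-human-codon tag back-translation, and the GenBank LOCUS
date fixed at a constant are all choices made for determinism: two
pipeline runs with the same config and seed produce byte-identical
outputs, which the suite asserts.

## Known limitations

* The shipped reference annotation (`inst/extdata/reference_rho_synthetic.yaml`)
  is a *synthetic* rhodopsin-like reference for self-contained operation
  and testing; the experimentally established bovine rhodopsin boundaries
  belong to the structural literature and are not hard-coded here, so the
  package does not fabricate them. For real designs, supply a curated
  reference YAML.
* The built-in aligner is pairwise-to-reference; a panel-wide MSA (e.g.
  MUSCLE) is ingested, not computed.
* Signal-peptide presence is a declared configuration, not predicted.
* Vector context (promoter, backbone) is metadata in the GenBank header,
  never sequence-modeled.
* Downstream statistics on assay endpoints (mixed models, post-hoc
  comparisons) are out of scope; outputs are tidy tables.

## A worked miniature

```{r}
ref <- make_toy_gpcr(toy_gpcr_spec(seed = 101), id = "RHO_synthetic")
don <- make_toy_gpcr(toy_gpcr_spec(seed = 10), id = "hM3Dq_toy")
acc <- make_toy_gpcr(toy_gpcr_spec(seed = 11), id = "B2AR_toy")

cfg <- run_config(ref$protein, ref$annotation, out_dir = tempfile("design"))
res <- run_design_pipeline(
  cfg, don$protein, acc$protein,
  donor_cds = back_translate(don$protein, "uniform-random", seed = 1),
  acceptor_cds = back_translate(acc$protein, "uniform-random", seed = 2))

res$construct
head(res$chimera$provenance)
res$flanking$donor
```
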