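---
title: "Homology-based plant miRNA discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based plant miRNA discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumir)
```

# The problem

Plant genomes — cereals especially — are large, repetitive and rich in
sequences that mimic microRNA precursors, so homology-based miRNA mining is
prone to false positives. `sumir` implements a conservative discovery chain:
candidate loci are found by sequence similarity to known mature miRNAs, kept
only if their genomic context folds into a qualifying hairpin holding a
plausible miRNA:miRNA\* duplex, and then annotated with independent lines of
in-silico evidence (expression support, contamination screens, and
transposable-element association, the classic confounder in cereals).

Every stage is implemented natively in the package — the similarity scan,
the thermodynamic folding, and the repeat-coverage computation included — so
the whole chain is deterministic, testable against independent oracles, and
free of external binaries.

# Stage models

## Homology scan

The scan finds **every** ungapped placement of every reference mature miRNA
on both strands of every contig with at most $k$ mismatches (default
$k = 2$). It is exhaustive by contract, not heuristic: overlapping and
co-located hits are all reported and deduplicated only later, and `N` in a
contig counts as a mismatch (an `N` inside a would-be mature is doomed at
the qualification stage anyway, so treating it as a wildcard would only
manufacture rejected candidates). The tested property is exact agreement
with a position-by-position brute-force comparator.

In small-RNA mode, reads are first matched against the references (default
ceiling 3 mismatches — the package exposes the stricter value 2 as an
argument, since both conventions are in circulation), the aligned part of
each read is trimmed out, and the trimmed sequences are rescanned against
the genome with zero mismatches.

## Folding

`fold_rna()` is a Zuker-style dynamic program over a simplified
nearest-neighbour model:

* stacking energies for the 36 ordered stacks of the six pair types
  (AU, UA, GC, CG, GU, UG), with values close to the standard
  nearest-neighbour tables;
* linear hairpin-loop penalty $5.0 + 0.11\,(L-3)$ kcal/mol, minimum loop 3;
* linear internal/bulge penalty $2.0 + 0.35\,s$ kcal/mol, capped at
  $s \le 30$ unpaired bases (larger internal loops are disallowed);
* linear multibranch penalty $3.4 + 0.4\,b + 0.1\,u$ kcal/mol for $b$
  branches and $u$ unpaired bases;
* `N` never pairs; pseudoknots are outside the model.

Energies are integers in 1/100 kcal/mol, so optima compare exactly: the
minimality of the returned energy is tested against exhaustive enumeration
of *all* pseudoknot-free structures for short sequences, and the returned
structure is always re-scored by `structure_energy()`, an independent
loop-decomposition evaluator that shares only the parameter table with the
DP.

The folding backend exists to make the pipeline's structural *decisions* —
arm assignment, duplex location, loop geometry — reproducible and testable;
it does not claim thermodynamic fidelity to any particular published
parameter set. Downstream code consumes only the pair table and energy, so
a full thermodynamic engine can be substituted without touching the rest of
the pipeline.

Among co-optimal structures a fixed deterministic backtracking order is
used (hairpin before the innermost-leftmost interior pair before the
leftmost multibranch split; in the exterior, 3′-unpaired before the
smallest 5′ pair index). This guarantees run-to-run identity of the pair
table; it approximates, but does not formally guarantee, the
lexicographically smallest co-optimal pair list.

## Duplex geometry

The star is derived from the pairing partners of the mature positions,
shifted by +2 toward the star's 3′ end — the canonical 2-nt 3′ overhang of
a Dicer product. A consequence worth stating explicitly: in a continuous
hairpin stem the 3′-terminal two nucleotides of the mature pair with
positions just *outside* the offset star (and vice versa). Those four
positions are therefore exempt from duplex-mismatch counting; otherwise
every canonical candidate would carry two spurious "mismatches" at each
duplex end and fail the Dicer-cut criterion. A **duplex mismatch** is a
non-exempt mature position that is unpaired or paired outside the star
interval; G·U wobble counts as paired, since it is structurally bona fide.

Candidates whose mature region has fewer than 60% of its positions paired
into one opposite arm are rejected before excision (`unstructured-mature`).
Zero-mismatch duplexes are flagged **suspect** — perfectly paired duplexes
are characteristic of inverted repeats and siRNA loci — and flow through a
separate output stream; they are judged with the same criteria but are not
merged into the main prediction list unless requested.

## Qualification

Each refolded precursor receives exactly one verdict:

* `Multiloop` — two or more helices branch from loops between the mature
  and the hairpin tip. One *linear* stem-loop above the mature is legal;
  it is branching that disqualifies.
* `Head` — mature or star extends into the terminal loop.
* `Dicer-cut` — a duplex mismatch within the first or last two duplex
  (non-overhang) positions of mature or star; the margin is an argument.
* `N-in-mature` — undetermined bases in the mature.
* `OK` otherwise.

When several criteria fail, the first in the order above is reported; the
order is a reporting convention, not a biological claim.

## Excision, refolding and statistics

The precursor spans from 20 nt beyond the near end of the mature to 20 nt
beyond the far end of the star, clipped at the window edges, and is
refolded; if the refold no longer holds the duplex the candidate is
rejected (`refold-lost-duplex`). The folding window itself reaches
`window_len / 2` (default 350) nt beyond each end of the hit, clipped at
contig ends.

Statistics use the standard definitions: AMFE $= \mathrm{MFE}/L \times
100$; MFEI $= |\mathrm{AMFE}| / \mathrm{GC\%}$, reported as a positive
magnitude, with GC computed over non-N residues and MFEI undefined at zero
GC. MFEI near or above 1 separates miRNA hairpins from tRNA/rRNA/mRNA
background (which sit near 0.6).

## Naming and redundancy

A single mature can match references from several families with different
mismatch sets; the fewest-mismatch annotation wins, exact ties keep all
tied ids comma-joined, and an optional precursor-level tiebreak picks the
family whose reference *precursor* aligns best. Names follow the arm-aware
rules (`miR156a-3p` + 3p arm → `miR156-3p`; `miR156a` + 3p → `miR156-3p`;
`miR156a-3p` + 5p arm → bare `miR156`), letter variants are stripped, and
repeated names are numbered `-1, -2, …` in discovery order. Letter-variant
assignment within families is deliberately out of scope — it requires
family-level analysis of precursor relationships.

## Evidence

All screens use strict thresholds exactly as documented, with boundary
behaviour unit-tested: contamination and precursor expression require
identity **and** query coverage strictly above 0.95; duplex expression
requires at least 3 exact, full-length read matches for the mature **and**
for any reserved star; TE-miR requires merged repeat coverage strictly
above 0.5 of the precursor; the siRNA-candidate rule requires one
alignment spanning at least 90% of the precursor with at most 3
mismatches. The 90% span floor is this package's operationalization of
"near-perfect complementarity" (the mismatch bound alone does not pin down
a span) and is exposed as an argument. Repeat alignments are ungapped and
counted from 80% identity over at least 20 nt — a coverage computation,
not a reproduction of any particular repeat-masking score scheme.

A small advisory statistic, the fraction of exact read alignments starting
inside the mature∪star intervals, summarizes whether read support is
concentrated (miRNA-like) or dispersed (siRNA-like) on the precursor.

## Target enrichment

Predicted targets arrive as an external table (tab-separated, psRNATarget
dialect). Per miRNA the winner minimizes the raw, unweighted sum
UPE + Expectation; ties go to the target whose exact annotation string is
most frequent across the whole annotated table, then to the smallest
target id. Annotations matching "uncharacterized", "hypothetical",
"predicted protein" or "unknown" (case-insensitive substrings,
configurable) are excluded, and miRNAs left with no annotated target are
reported with `NA`. Exact-string abundance counting is the documented
choice; GO-level grouping would need an ontology and is out of scope.

# The synthetic-data generator

`make_precursor()` builds hairpins with a known truth: the mature on a
chosen arm, a designed continuous stem with a 12-nt basal stem below the
duplex (genuine pre-miRNAs carry basal stems — and without one, a planted
hairpin is frequently absorbed into background structure when a 700-nt
window is folded), a 2-nt 3′ tail, A/C-biased loop, designed duplex
mismatches created by substituting the star-side partner base to one that
neither pairs canonically nor wobbles, and optionally one defect per
structural verdict class. `make_genome()` plants precursors and repeat
copies at recorded, non-overlapping loci on recorded strands in an i.i.d.
background (default GC 0.44, a typical grass genome);
`make_reads()` emits exact-embedding reads at requested depths plus random
noise. Everything is deterministic per seed.

What the generator does *not* emulate: a realistic repeat landscape,
indels and assembly artefacts, sequence-composition structure beyond GC,
polyploid homoeologs, and expression biases. Passing tests on these
fixtures therefore demonstrate the correctness of the pipeline's decisions
under its stated model, not field performance on real cereal genomes.

The `basic` preset (50 defect-free precursors from 25 families planted in
100 kb) is the recovery benchmark: the pipeline is expected to recover at
least 90% of planted matures with zero family misassignment, and the
locator to find every planted locus exactly. Problem sizes throughout the
test-suite (100-kb genomes, hundreds of scan instances, enumeration up to
22 nt) were chosen so the full suite exercises every stage at depth while
staying quick on a laptop.

# Numerical and degenerate-input choices

* Coordinates are 1-based and fully closed everywhere; antisense features
  are reported on forward-strand coordinates with a strand label.
* The internal canonical alphabet is RNA; DNA input converts on ingestion.
* References containing `N` are skipped with a warning (a 20-nt query with
  an undetermined base cannot be matched meaningfully).
* Zero hits, empty reference or evidence databases, precursors absent from
  the contigs, and zero-GC precursors all degrade to explicit empty/NA
  results rather than errors.
* Output ordering is fixed (lexicographic hit order, stable prediction
  indices), so reruns are byte-identical — which is itself a tested
  property.

# Known limitations

* The energy model is simplified; absolute MFE values differ from full
  Turner-model engines, so MFE/MFEI summaries are comparable within runs
  of this package, not across folding engines.
* Exhaustive scanning is quadratic in genome size times reference count;
  it is comfortable for contigs and test genomes, while multi-Gbp
  assemblies would call for a seeded index front end (with the same
  exhaustive contract).
* Ungapped alignment throughout: diverged repeats or spliced precursors
  with indels relative to the reference are out of reach by design; for
  transcriptome mode the package emits precursor FASTA suitable for an
  external splice-aware aligner rather than attempting splice-aware
  mapping itself.
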