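# sumir

Homology-based discovery and characterization of plant microRNAs, for
researchers mining genomic or transcriptomic contigs of plants — cereals in
particular, where huge, repeat-rich genomes make miRNA identification
highly prone to false positives.

## What it computes

Given contigs and a reference list of known mature miRNAs (miRBase-style
ids), `sumir` runs a conservative discovery chain, every stage implemented
natively in the package:

1. **Homology scan** — every ungapped placement of every reference on both
   strands with ≤ *k* mismatches (default 2); exhaustive by contract and
   tested against a brute-force comparator.
2. **Hairpin folding** — the sequence around each hit is folded by a
   built-in Zuker-style minimum-free-energy dynamic program
   (nearest-neighbour stacking, linear loop penalties, G·U wobble, no
   pseudoknots), and the miRNA:miRNA\* duplex is located from the pairing
   partners of the mature with the canonical 2-nt 3′ overhang. Perfect
   (zero-mismatch) duplexes are routed separately as *suspects* — likely
   inverted repeats or siRNAs.
3. **Qualification** — one verdict per candidate: `OK`, or `Multiloop`
   (branched structure above the mature), `Head` (mature/star in the
   terminal loop), `Dicer-cut` (mismatch at the Dicer cut positions),
   `N-in-mature`. Redundant annotations resolve to the closest homolog and
   names follow the arm-aware rules (`miR156a-3p` + 3p arm → `miR156-3p`;
   no suffix → detected arm; opposite arm → bare `miR156`).
4. **Location & representation** — exact loci of every unique precursor on
   both strands; family representation counts one unit per locus plus
   extra units for single-locus precursors encoding several distinct
   matures.
5. **Evidence** — non-coding-RNA and organellar contamination screens
   (> 95% identity and coverage), in-silico expression at precursor
   (> 95%/95% against transcripts) and duplex level (≥ 3 exact small-RNA
   reads on mature *and* star), and TE classification (TE-miR at > 50%
   merged repeat coverage; siRNA candidate at ≤ 3 mismatches over ≥ 90% of
   the precursor).
6. **Target enrichment** — from a psRNATarget-dialect table, the most
   significant annotated target per miRNA by minimal UPE + Expectation,
   ties broken by annotation abundance.

Key statistics per precursor: MFE, AMFE = MFE/length × 100, and
MFEI = |AMFE| / GC% — the classic discriminator of miRNA hairpins (≈ 1.0+)
from tRNA/rRNA/mRNA background (≈ 0.6).

A synthetic-data generator (`make_precursor()`, `make_genome()`,
`make_reads()`, `fixture_preset()`) plants known-truth precursors, repeats
and reads into toy genomes so the whole chain is testable without
downloads.

## Worked example

```r
library(sumir)

fx  <- fixture_preset("srna", seed = 42)        # 10 planted precursors + reads
run <- run_pipeline(fx$contigs, fx$refs, sumir_config(), reads = fx$reads)
run
#> <sumir_run> 0.021 Mbp input | 20 hits -> 17 hairpins (+3 suspects) -> 17 miRNAs in 10 families

dplyr::select(tidy(run), assigned_name, mature, length, mfe, mfei)[1:3, ]
#>   assigned_name mature                length   mfe  mfei
#> 1 miR156-5p-1   GGCACAAAGAAGCAUCCUCCC    104 -75.0  1.42
#> 2 miR156-5p-2   GGCACAAAGUAGCAUCCUCCC    104 -78.6  1.45
#> 3 miR157-3p-1   GUGAUUAAGUAGCUGUCGAAG    100 -66.9  1.49

glance(run)[, c("predicted_mirnas", "families", "mean_mfe", "mean_mfei")]
#>   predicted_mirnas families mean_mfe mean_mfei
#> 1               17       10    -70.9      1.32

run$evidence[1, c("name", "mature_reads", "star_reads", "duplex_expressed")]
#>   name        mature_reads star_reads duplex_expressed
#> 1 miR156-5p-1            5          5 TRUE

fold_rna(run$predicted$precursor[1])
#> <sumir_fold> 104 nt, MFE -75.03 kcal/mol (builtin)
#> UACAUCAAUUUUCUCCGGUGGGCACAAAGAAGCAUCCUCCCGCCGGCAAAAAAAAACCGGCGGGAGGAUGCUACUUUGUGCCCACCGGAGAAAAAAUACUCCAG
#> ........(((((((((((((((((((((.((((((((((((((((..........)))))))))))))))).)))))))))))))))))))))..........
```

The 20 scan hits include each planted mature on its own arm *and* its
near-reverse-complement placement on the star arm; qualification and
redundancy resolution reduce these to 17 named predictions (3 perfect
duplexes were separated as suspects), all with read-supported duplexes and
MFEI in the miRNA regime. `out_dir =` makes `run_pipeline()` write the
stage tables (`hits.csv`, `pre-miRNA-location.csv`, `pre-miRNA-count.csv`,
`expression.tbl`, `evidence.csv`, `summary.csv`, a separate `suspects/`
stream, and the serialized configuration) byte-reproducibly.

A thin command-line front end lives at `inst/scripts/sumir.R`
(`find`, `targets`, `fixtures`, `run` subcommands).

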