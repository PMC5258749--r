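Package: sumir
Title: Homology-Based Discovery and Characterization of Plant miRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies plant microRNA candidates in genomic or transcriptomic
    contigs by homology to known mature miRNAs, folds the flanking sequence
    into a minimum-free-energy hairpin, locates the miRNA:miRNA* duplex,
    qualifies candidates against structural precursor criteria (multibranched
    loops, head overlap, Dicer-cut mismatches), resolves redundant annotations
    and assigns arm-aware names. Downstream stages map unique precursors back
    to their loci with strand-aware family representation counts, attach
    in-silico evidence (non-coding RNA and organellar contamination screens,
    precursor and mature/star expression support from small-RNA reads,
    transposable-element coverage with TE-miR versus siRNA-candidate
    discrimination) and rank predicted targets by the sum of binding energy
    and expectation scores. Includes a synthetic-data generator that plants
    known-truth precursors, repeats and reads into toy genomes so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
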