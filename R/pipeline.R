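#' Pipeline configuration
#'
#' Collects every stage threshold with its default, for provenance: the
#' configuration is serialized into each output directory.
#'
#' @param max_mismatch Homology-scan mismatch ceiling (default 2).
#' @param srna_max_mismatch Read-to-reference ceiling in small-RNA mode
#'   (default 3).
#' @param window_len Folding window length (default 700).
#' @param flank Precursor excision flank (default 20).
#' @param dicer_margin Dicer cut-region width (default 2).
#' @param id_min,cov_min Identity/coverage thresholds for the contamination
#'   and precursor-expression screens (default 0.95).
#' @param read_min Minimum supporting reads per duplex side (default 3).
#' @param te_cov TE coverage threshold (default 0.5).
#' @param sirna_mismatch,sirna_span siRNA-candidate rule (defaults 3, 0.9).
#' @param include_suspects Merge suspects into the main prediction list
#'   (default FALSE; they are written to a separate sub-directory).
#' @param seed Seed recorded for provenance.
#' @return A named list of class `sumir_config`.
#' @export
sumir_config <- function(max_mismatch = 2L, srna_max_mismatch = 3L,
                         window_len = 700L, flank = 20L, dicer_margin = 2L,
                         id_min = 0.95, cov_min = 0.95, read_min = 3L,
                         te_cov = 0.5, sirna_mismatch = 3L, sirna_span = 0.9,
                         include_suspects = FALSE, seed = 1L) {
  structure(list(max_mismatch = max_mismatch,
                 srna_max_mismatch = srna_max_mismatch,
                 window_len = window_len, flank = flank,
                 dicer_margin = dicer_margin, id_min = id_min,
                 cov_min = cov_min, read_min = read_min, te_cov = te_cov,
                 sirna_mismatch = sirna_mismatch, sirna_span = sirna_span,
                 include_suspects = include_suspects, seed = seed),
            class = "sumir_config")
}

#' Run the whole discovery pipeline
#'
#' Orchestrates the stages - homology scan, hairpin folding and duplex
#' assessment, qualification and naming, location/representation, and the
#' evidence screens - and (optionally) writes the stage outputs to a
#' directory: `hits.csv`, `hairpins.csv`, `suspects/suspects.csv`,
#' `predicted.csv`, `pre-miRNA-location.csv`, `pre-miRNA-count.csv`,
#' `expression.tbl`, `evidence.csv`, `summary.csv` and `config.txt`.
#' Outputs are byte-reproducible: rerunning with the same inputs and
#' configuration writes identical files.
#'
#' @param contigs Contig tibble (or path to a FASTA file).
#' @param refs Reference mature miRNA tibble (or FASTA path).
#' @param config A [sumir_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param ncrna_db,organellar_db,transcripts,reads,repeat_db,ref_precursors
#'   Optional evidence inputs (tibbles or FASTA/FASTQ paths).
#' @return An object of class `sumir_run`: list with `hits`, `candidates`,
#'   `judged`, `suspects`, `predicted`, `locations`, `representation`,
#'   `evidence`, `summary` and `config`.
#' @export
run_pipeline <- function(contigs, refs, config = sumir_config(),
                         out_dir = NULL, ncrna_db = NULL,
                         organellar_db = NULL, transcripts = NULL,
                         reads = NULL, repeat_db = NULL,
                         ref_precursors = NULL) {
  as_seqs <- function(x, reader = read_fasta) {
    if (is.character(x) && length(x) == 1L) reader(x) else x
  }
  contigs <- as_seqs(contigs)
  refs <- as_seqs(refs)
  ncrna_db <- as_seqs(ncrna_db)
  organellar_db <- as_seqs(organellar_db)
  transcripts <- as_seqs(transcripts)
  reads <- as_seqs(reads, read_reads)
  repeat_db <- as_seqs(repeat_db)
  ref_precursors <- as_seqs(ref_precursors)

  hits <- scan_mirna_hits(contigs, refs, config$max_mismatch)
  candidates <- if (nrow(hits)) {
    fold_hairpins(hits, contigs, config$window_len, config$flank)
  } else {
    tibble::tibble()
  }
  judged <- if (nrow(candidates)) {
    judge_candidates(candidates, config$dicer_margin)
  } else {
    candidates
  }
  hairpins <- if (nrow(judged)) dplyr::filter(judged, .data$status == "ok")
              else judged
  suspects <- if (nrow(hairpins) && "suspect" %in% names(hairpins)) {
    dplyr::filter(hairpins, .data$suspect)
  } else {
    hairpins
  }
  n_suspects <- nrow(suspects)
  predicted <- predict_mirnas(judged_or_empty(judged), ref_precursors,
                              include_suspects = config$include_suspects)
  locations <- if (nrow(predicted)) locate_precursors(predicted, contigs)
               else tibble::tibble(precursor_id = character(),
                                   family = character(),
                                   contig_id = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), found = logical())
  representation <- family_representation(locations, predicted)
  evid <- if (nrow(predicted)) {
    evidence_table(predicted, ncrna_db, organellar_db, transcripts, reads,
                   repeat_db, config$read_min, config$id_min,
                   config$cov_min, config$te_cov, config$sirna_mismatch,
                   config$sirna_span)
  } else {
    tibble::tibble()
  }
  summary <- tibble::tibble(
    input_mbp = sum(nchar(contigs$residues)) / 1e6,
    find_hits = nrow(hits),
    fold_hairpins = nrow(hairpins) - n_suspects,
    suspects = n_suspects,
    predicted_mirnas = nrow(predicted),
    families = length(unique(predicted$family))
  )
  run <- structure(list(hits = hits, candidates = candidates,
                        judged = judged, suspects = suspects,
                        predicted = predicted, locations = locations,
                        representation = representation, evidence = evid,
                        summary = summary, config = config),
                   class = "sumir_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

judged_or_empty <- function(judged) {
  if (nrow(judged) == 0L || !"verdict" %in% names(judged)) {
    tibble::tibble(verdict = character(), suspect = logical())
  } else {
    judged
  }
}

drop_list_cols <- function(tbl) {
  if (nrow(tbl) == 0L) return(tbl)
  keep <- !vapply(tbl, is.list, logical(1))
  tbl[, keep, drop = FALSE]
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "suspects"), showWarnings = FALSE)
  wr <- function(tbl, name) {
    readr::write_csv(drop_list_cols(tbl), file.path(out_dir, name))
  }
  hits_out <- run$hits
  if (nrow(hits_out)) {
    hits_out$mismatch_positions <- vapply(hits_out$mismatch_positions,
                                          paste, character(1), collapse = ";")
  }
  wr(hits_out, "hits.csv")
  wr(run$judged, "hairpins.csv")
  readr::write_csv(drop_list_cols(run$suspects),
                   file.path(out_dir, "suspects", "suspects.csv"))
  wr(run$predicted, "predicted.csv")
  wr(run$locations, "pre-miRNA-location.csv")
  wr(run$representation$family_counts, "pre-miRNA-count.csv")
  expr <- if (nrow(run$predicted)) {
    run$predicted[, c("assigned_name", "mature", "star_list")]
  } else {
    tibble::tibble(assigned_name = character(), mature = character(),
                   star_list = character())
  }
  readr::write_tsv(expr, file.path(out_dir, "expression.tbl"))
  wr(run$evidence, "evidence.csv")
  wr(run$summary, "summary.csv")
  cfg <- run$config
  readr::write_lines(paste0(names(cfg), "=", vapply(cfg, as.character,
                                                    character(1))),
                     file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' @export
print.sumir_run <- function(x, ...) {
  s <- x$summary
  cat("<sumir_run> ", round(s$input_mbp, 3), " Mbp input | ",
      s$find_hits, " hits -> ", s$fold_hairpins, " hairpins (+",
      s$suspects, " suspects) -> ", s$predicted_mirnas, " miRNAs in ",
      s$families, " families\n", sep = "")
  invisible(x)
}
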