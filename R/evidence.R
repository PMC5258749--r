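# Best ungapped placement of query against subject (both strands), returning
# identity, coverage and mismatches of the best-identity placement among
# those meeting the coverage floor.
best_ungapped <- function(query, subject, cov_min = 0.95) {
  lq <- nchar(query)
  min_span <- max(1L, as.integer(ceiling(cov_min * lq)) )
  best <- NULL
  for (subj in c(subject, revcomp(subject))) {
    h <- ungapped_hits_cpp(as_rna(query), as_rna(subj), min_span, 0)
    if (nrow(h) == 0L) next
    h$identity <- h$matches / h$span
    h$coverage <- h$span / lq
    top <- h[order(-h$identity, -h$coverage), ][1, ]
    if (is.null(best) || top$identity > best$identity) best <- top
  }
  best
}

#' Screen predictions against contaminant databases
#'
#' A prediction is flagged when the best local ungapped match of its mature
#' *or* precursor against the database exceeds both the identity and the
#' query-coverage threshold (strictly greater, so a 95.0% hit does not
#' flag at the default 0.95). Flagged records are separated downstream,
#' never silently dropped.
#'
#' @param predicted Tibble from [predict_mirnas()].
#' @param db Contaminant sequence tibble (non-coding RNAs or organellar
#'   genomes); `NULL` or empty skips the screen (all `FALSE`).
#' @param id_min,cov_min Identity and query-coverage thresholds
#'   (default 0.95, exceeded strictly).
#' @return Logical vector, one flag per prediction row.
#' @export
screen_contaminants <- function(predicted, db, id_min = 0.95,
                                cov_min = 0.95) {
  if (is.null(db) || nrow(db) == 0L) return(rep(FALSE, nrow(predicted)))
  purrr::map2_lgl(predicted$mature, predicted$precursor, function(mat, pre) {
    any(vapply(db$residues, function(s) {
      for (q in c(mat, pre)) {
        b <- best_ungapped(q, s, cov_min)
        if (!is.null(b) && b$identity > id_min && b$coverage > cov_min)
          return(TRUE)
      }
      FALSE
    }, logical(1)))
  })
}

#' In-silico precursor expression
#'
#' A precursor is "expressed" when some transcript or EST contains it at
#' more than `min_identity` identity over more than `min_coverage` of the
#' precursor length (both strictly greater).
#'
#' @param precursors Character vector of precursor sequences.
#' @param transcripts Transcript/EST tibble; `NULL` or empty gives all
#'   `FALSE`.
#' @param min_identity,min_coverage Thresholds (default 0.95).
#' @return Logical vector per precursor.
#' @export
precursor_expression <- function(precursors, transcripts,
                                 min_identity = 0.95, min_coverage = 0.95) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    return(rep(FALSE, length(precursors)))
  vapply(precursors, function(pre) {
    any(vapply(transcripts$residues, function(s) {
      b <- best_ungapped(pre, s, min_coverage)
      !is.null(b) && b$identity > min_identity && b$coverage > min_coverage
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Mature/star expression support from small-RNA reads
#'
#' A read supports a sequence iff the full mature (or star) occurs exactly
#' within the read (100% query identity and coverage); counts are read
#' counts. Any of the reserved stars may supply star support. The duplex is
#' "in-silico expressed" when both mature and star reach `read_min` reads.
#'
#' @param predicted Tibble with `mature` and `star_list` (semicolon-joined)
#'   columns.
#' @param reads Read tibble from [read_reads()]; `NULL`/empty gives zero
#'   counts.
#' @param read_min Minimum supporting reads per duplex side (default 3).
#' @return Tibble `mature_reads`, `star_reads`, `duplex_expressed`.
#' @export
mature_expression <- function(predicted, reads, read_min = 3L) {
  n <- nrow(predicted)
  if (is.null(reads) || nrow(reads) == 0L) {
    return(tibble::tibble(mature_reads = rep(0L, n), star_reads = rep(0L, n),
                          duplex_expressed = rep(FALSE, n)))
  }
  rs <- as_rna(reads$residues)
  count_reads <- function(q) {
    if (!nzchar(q)) return(0L)
    sum(stringr::str_detect(rs, stringr::fixed(q)))
  }
  mature_reads <- vapply(as_rna(predicted$mature), count_reads, integer(1),
                         USE.NAMES = FALSE)
  star_reads <- vapply(predicted$star_list, function(sl) {
    stars <- strsplit(as_rna(sl), ";", fixed = TRUE)[[1]]
    if (length(stars) == 0L) return(0L)
    max(vapply(stars, count_reads, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(mature_reads = mature_reads, star_reads = star_reads,
                 duplex_expressed = mature_reads >= read_min &
                   star_reads >= read_min)
}

#' Classify precursors against a repeat library
#'
#' Replaces the external repeat-masking step: ungapped alignments of each
#' repeat (both strands) against the precursor, seeded at `seed_identity`
#' identity over at least `min_span` nt, are merged on the precursor axis.
#' Precursors covered on more than `te_cov` of their length are TE-miRs;
#' a single alignment spanning at least `sirna_span` of the precursor with
#' at most `sirna_mismatch` mismatches marks a potential siRNA candidate.
#' `te_family` is taken from the largest-coverage repeat, parsed from the
#' RepeatMasker-style `name#family` id convention when present.
#'
#' @param precursors Character vector of precursor sequences.
#' @param repeat_db Repeat tibble (`id`, `residues`); `NULL`/empty gives
#'   all-FALSE classifications.
#' @param te_cov Coverage fraction that must be exceeded (default 0.5).
#' @param sirna_mismatch Mismatch ceiling for the siRNA rule (default 3).
#' @param sirna_span Minimum aligned span fraction for the siRNA rule
#'   (default 0.9).
#' @param seed_identity Minimum identity of a counted alignment
#'   (default 0.8).
#' @param min_span Minimum aligned span in nt (default 20).
#' @return Tibble `te_coverage_fraction`, `te_mir`, `sirna_candidate`,
#'   `te_family`.
#' @export
classify_te <- function(precursors, repeat_db, te_cov = 0.5,
                        sirna_mismatch = 3L, sirna_span = 0.9,
                        seed_identity = 0.8, min_span = 20L) {
  n <- length(precursors)
  if (is.null(repeat_db) || nrow(repeat_db) == 0L) {
    return(tibble::tibble(te_coverage_fraction = rep(0, n),
                          te_mir = rep(FALSE, n),
                          sirna_candidate = rep(FALSE, n),
                          te_family = rep("", n)))
  }
  te_family_of <- function(id) {
    if (grepl("#", id, fixed = TRUE)) sub("^.*#", "", id) else id
  }
  rows <- purrr::map(precursors, function(pre) {
    lp <- nchar(pre)
    per_repeat <- purrr::map2(repeat_db$id, repeat_db$residues,
                              function(rid, rep_seq) {
      hits <- dplyr::bind_rows(
        ungapped_hits_cpp(as_rna(pre), as_rna(rep_seq), min_span,
                          seed_identity),
        ungapped_hits_cpp(as_rna(pre), revcomp(rep_seq), min_span,
                          seed_identity))
      if (nrow(hits) == 0L) return(NULL)
      dplyr::mutate(hits, repeat_id = rid)
    })
    hits <- dplyr::bind_rows(per_repeat)
    if (nrow(hits) == 0L) {
      return(tibble::tibble(te_coverage_fraction = 0, te_mir = FALSE,
                            sirna_candidate = FALSE, te_family = ""))
    }
    cov <- merge_intervals(tibble::tibble(seq_id = "pre",
                                          start = hits$q_start,
                                          end = hits$q_end))$covered / lp
    sirna <- any(hits$span >= sirna_span * lp &
                   (hits$span - hits$matches) <= sirna_mismatch)
    by_repeat <- split(hits, hits$repeat_id)
    cov_by <- vapply(by_repeat, function(h)
      merge_intervals(tibble::tibble(seq_id = "pre", start = h$q_start,
                                     end = h$q_end))$covered, integer(1))
    top <- names(cov_by)[order(-cov_by, names(cov_by))][1]
    tibble::tibble(te_coverage_fraction = cov, te_mir = cov > te_cov,
                   sirna_candidate = sirna,
                   te_family = te_family_of(top))
  })
  dplyr::bind_rows(rows)
}

#' Assemble the per-miRNA evidence table
#'
#' Runs all evidence screens and returns one row per predicted miRNA with
#' contamination flags, expression support and TE classification. The
#' advisory read-dispersion statistic is the fraction of read alignments
#' (exact read occurrences on the precursor) whose start falls inside the
#' mature or star interval; concentrated values support a genuine miRNA,
#' dispersed values an siRNA origin.
#'
#' @param predicted Tibble from [predict_mirnas()].
#' @param ncrna_db,organellar_db,transcripts,reads,repeat_db Optional
#'   evidence inputs (sequence tibbles); `NULL` skips the respective
#'   screen.
#' @param read_min,id_min,cov_min,te_cov,sirna_mismatch,sirna_span
#'   Thresholds, see the individual screens.
#' @return A tibble: `name`, `ncRNA_hit`, `organellar_hit`,
#'   `precursor_expressed`, `mature_reads`, `star_reads`,
#'   `duplex_expressed`, `te_coverage_fraction`, `te_mir`,
#'   `sirna_candidate`, `te_family`, `duplex_read_fraction`.
#' @export
evidence_table <- function(predicted, ncrna_db = NULL, organellar_db = NULL,
                           transcripts = NULL, reads = NULL,
                           repeat_db = NULL, read_min = 3L, id_min = 0.95,
                           cov_min = 0.95, te_cov = 0.5,
                           sirna_mismatch = 3L, sirna_span = 0.9) {
  expr <- mature_expression(predicted, reads, read_min)
  te <- classify_te(predicted$precursor, repeat_db, te_cov,
                    sirna_mismatch, sirna_span)
  disp <- duplex_read_fraction(predicted, reads)
  tibble::tibble(
    name = predicted$assigned_name,
    ncRNA_hit = screen_contaminants(predicted, ncrna_db, id_min, cov_min),
    organellar_hit = screen_contaminants(predicted, organellar_db, id_min,
                                         cov_min),
    precursor_expressed = precursor_expression(predicted$precursor,
                                               transcripts, id_min, cov_min),
    mature_reads = expr$mature_reads,
    star_reads = expr$star_reads,
    duplex_expressed = expr$duplex_expressed,
    te_coverage_fraction = te$te_coverage_fraction,
    te_mir = te$te_mir,
    sirna_candidate = te$sirna_candidate,
    te_family = te$te_family,
    duplex_read_fraction = disp
  )
}

# Fraction of exact read alignments on the precursor that start inside the
# mature or star interval (advisory dispersion statistic; NA without reads
# or without alignments).
duplex_read_fraction <- function(predicted, reads) {
  n <- nrow(predicted)
  if (is.null(reads) || nrow(reads) == 0L) return(rep(NA_real_, n))
  rs <- unique(as_rna(reads$residues))
  purrr::pmap_dbl(predicted[, c("precursor", "mature_start", "mature_end",
                                "star_start", "star_end")],
                  function(precursor, mature_start, mature_end,
                           star_start, star_end) {
    starts <- integer(0)
    for (r in rs) {
      if (nchar(r) > nchar(precursor)) next
      h <- mismatch_scan_cpp(as_rna(precursor), r, 0L)
      starts <- c(starts, h$start)
    }
    if (length(starts) == 0L) return(NA_real_)
    inside <- (starts >= mature_start & starts <= mature_end) |
      (starts >= star_start & starts <= star_end)
    mean(inside)
  })
}
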