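#' Scan contigs for homologs of reference mature miRNAs
#'
#' Finds every ungapped placement of every reference sequence, on both
#' strands of every contig, with at most `max_mismatch` mismatches. The scan
#' is exhaustive: overlapping and co-located hits are all retained
#' (deduplication happens later, at the qualification stage). `N` in a
#' contig counts as a mismatch at that position. Sequences are compared in
#' the RNA alphabet regardless of input alphabet.
#'
#' @param contigs Sequence tibble (`id`, `residues`), e.g. from
#'   [read_fasta()].
#' @param refs Reference mature miRNAs as a sequence tibble; ids should be
#'   miRBase-style (see [parse_mirna_id()]). References of length outside
#'   18-26 nt are rejected; references containing `N` are skipped with a
#'   warning.
#' @param max_mismatch Maximum number of mismatches (default 2).
#' @param ref_length_range Acceptable reference lengths as `c(min, max)`
#'   (default 18-26 nt, the mature-miRNA range). Trimmed small-RNA queries
#'   may need a wider range.
#' @return A tibble with one row per hit: `contig_id`, `start`, `end`
#'   (1-based closed, forward-strand coordinates of the contig), `strand`
#'   (`"sense"`/`"antisense"`), `ref_id`, `mismatches`,
#'   `mismatch_positions` (list of 1-based positions within the reference,
#'   5'->3' of the reference) and `mature` (the matched contig segment read
#'   5'->3' on its strand, RNA alphabet). Rows are sorted by
#'   (contig, position, reference).
#' @export
scan_mirna_hits <- function(contigs, refs, max_mismatch = 2L,
                            ref_length_range = c(18L, 26L)) {
  stopifnot(max_mismatch >= 0L, nrow(refs) > 0L)
  refs <- dplyr::mutate(refs, residues = as_rna(.data$residues))
  has_n <- grepl("N", refs$residues, fixed = TRUE)
  if (any(has_n)) {
    warning("skipping reference(s) containing N: ",
            paste(refs$id[has_n], collapse = ", "), call. = FALSE)
    refs <- refs[!has_n, , drop = FALSE]
  }
  len_ok <- nchar(refs$residues) >= ref_length_range[1] &
    nchar(refs$residues) <= ref_length_range[2]
  if (!all(len_ok)) {
    stop("reference length outside 18-26 nt: ",
         paste(refs$id[!len_ok], collapse = ", "), call. = FALSE)
  }
  out <- purrr::pmap(list(contigs$id, as_rna(contigs$residues)),
                     function(cid, fwd) {
    L <- nchar(fwd)
    rev <- revcomp(fwd)
    purrr::pmap(list(refs$id, refs$residues), function(rid, ref) {
      m <- nchar(ref)
      rows <- list()
      hs <- mismatch_scan_cpp(fwd, ref, max_mismatch)
      if (length(hs$start)) {
        rows$sense <- tibble::tibble(
          contig_id = cid, start = hs$start, end = hs$start + m - 1L,
          strand = "sense", ref_id = rid, mismatches = hs$mismatches,
          mismatch_positions = hs$positions,
          mature = substring(fwd, hs$start, hs$start + m - 1L))
      }
      ha <- mismatch_scan_cpp(rev, ref, max_mismatch)
      if (length(ha$start)) {
        # position x..y on the reverse-complement maps to L-y+1..L-x+1 forward
        rows$anti <- tibble::tibble(
          contig_id = cid, start = L - (ha$start + m - 1L) + 1L,
          end = L - ha$start + 1L,
          strand = "antisense", ref_id = rid, mismatches = ha$mismatches,
          mismatch_positions = ha$positions,
          mature = substring(rev, ha$start, ha$start + m - 1L))
      }
      dplyr::bind_rows(rows)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          ref_id = character(), mismatches = integer(),
                          mismatch_positions = list(), mature = character()))
  }
  dplyr::arrange(out, .data$contig_id, .data$start, .data$ref_id, .data$strand)
}

#' Match small-RNA reads against reference miRNAs
#'
#' For each (read, reference) pair, reports the best (fewest-mismatch,
#' leftmost) ungapped placement of the full reference inside the read when
#' the read is at least as long as the reference. Shorter reads are instead
#' placed inside the reference, requiring the full read to align. Pairs
#' exceeding `max_mismatch` produce no row.
#'
#' @param reads Read tibble from [read_reads()].
#' @param refs Reference miRNA tibble.
#' @param max_mismatch Mismatch ceiling (default 3, the small-RNA mode
#'   default; pass 2 for the stricter setting).
#' @return Tibble with `read_id`, `ref_id`, `read_start`, `read_end`
#'   (matched sub-interval of the read), `mismatches`.
#' @export
match_reads_to_refs <- function(reads, refs, max_mismatch = 3L) {
  reads <- dplyr::mutate(reads, residues = as_rna(.data$residues))
  refs <- dplyr::mutate(refs, residues = as_rna(.data$residues))
  grid <- tidyr::expand_grid(ri = seq_len(nrow(reads)), fi = seq_len(nrow(refs)))
  rows <- purrr::pmap(grid, function(ri, fi) {
    rd <- reads$residues[ri]; rf <- refs$residues[fi]
    if (nchar(rd) >= nchar(rf)) {
      bp <- best_placement_cpp(rd, rf)
      if (bp[1] < 0 || bp[2] > max_mismatch) return(NULL)
      tibble::tibble(read_id = reads$id[ri], ref_id = refs$id[fi],
                     read_start = bp[1], read_end = bp[1] + nchar(rf) - 1L,
                     mismatches = bp[2])
    } else {
      bp <- best_placement_cpp(rf, rd)
      if (bp[1] < 0 || bp[2] > max_mismatch) return(NULL)
      tibble::tibble(read_id = reads$id[ri], ref_id = refs$id[fi],
                     read_start = 1L, read_end = nchar(rd),
                     mismatches = bp[2])
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(read_id = character(), ref_id = character(),
                          read_start = integer(), read_end = integer(),
                          mismatches = integer()))
  }
  out
}

#' Trim matched reads to their reference-aligned part
#'
#' The matched substring of each read becomes a new query record; the id
#' records both the read and the reference it matched. These trimmed records
#' are intended to be rescanned against the genome with
#' `scan_mirna_hits(..., max_mismatch = 0)`.
#'
#' @param matches Output of [match_reads_to_refs()].
#' @param reads The read tibble the matches came from.
#' @return A sequence tibble (`id`, `description`, `residues`).
#' @export
trim_to_match <- function(matches, reads) {
  res <- setNames(as_rna(reads$residues), reads$id)
  tibble::tibble(
    id = paste0(matches$read_id, "|", matches$ref_id),
    description = "",
    residues = unname(substring(res[matches$read_id], matches$read_start,
                                matches$read_end))
  )
}
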