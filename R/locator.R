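#' Locate unique precursors across the contigs
#'
#' Finds every exact (0-mismatch) occurrence of every unique precursor
#' sequence on both strands of the contigs, including overlapping
#' occurrences; palindromic self-hits are deduplicated by
#' (contig, start, end, strand). Precursors absent from the contigs yield a
#' warning row rather than an error.
#'
#' @param predicted Tibble from [predict_mirnas()] (needs `assigned_name`,
#'   `family`, `precursor`).
#' @param contigs Contig tibble the miRNAs were mined from.
#' @return A tibble `precursor_id`, `family`, `contig_id`, `start`, `end`,
#'   `strand`, `found` (FALSE rows mark precursors with no exact locus).
#' @export
locate_precursors <- function(predicted, contigs) {
  uniq <- predicted |>
    dplyr::distinct(.data$precursor, .keep_all = TRUE) |>
    dplyr::select(precursor_id = "assigned_name", "family", "precursor")
  fwd <- as_rna(contigs$residues)
  rows <- purrr::pmap(uniq, function(precursor_id, family, precursor) {
    hits <- purrr::map2(contigs$id, fwd, function(cid, seq) {
      L <- nchar(seq)
      m <- nchar(precursor)
      s <- mismatch_scan_cpp(seq, precursor, 0L)
      a <- mismatch_scan_cpp(revcomp(seq), precursor, 0L)
      dplyr::bind_rows(
        if (length(s$start))
          tibble::tibble(contig_id = cid, start = s$start,
                         end = s$start + m - 1L, strand = "sense"),
        if (length(a$start))
          tibble::tibble(contig_id = cid, start = L - (a$start + m - 1L) + 1L,
                         end = L - a$start + 1L, strand = "antisense")
      )
    }) |> dplyr::bind_rows()
    if (nrow(hits) == 0L) {
      warning("precursor not found in contigs: ", precursor_id,
              call. = FALSE)
      return(tibble::tibble(precursor_id = precursor_id, family = family,
                            contig_id = NA_character_, start = NA_integer_,
                            end = NA_integer_, strand = NA_character_,
                            found = FALSE))
    }
    hits |>
      dplyr::distinct(.data$contig_id, .data$start, .data$end, .data$strand) |>
      dplyr::mutate(precursor_id = precursor_id, family = family,
                    found = TRUE)
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("precursor_id", "family") |>
    dplyr::arrange(.data$precursor_id, .data$contig_id, .data$start,
                   .data$strand)
}

#' Family representation counts
#'
#' One representation unit per located precursor occurrence, plus one extra
#' unit per additional distinct mature miRNA carried by a single-locus
#' precursor (a precursor encoding two distinct matures of a family counts
#' twice). Also tabulates which families occur on which contig.
#'
#' @param locations Tibble from [locate_precursors()].
#' @param predicted The predicted miRNA tibble (to count distinct matures
#'   per precursor).
#' @return A list with `family_counts` (tibble `family`, `count`),
#'   `contig_families` (tibble `contig_id`, `families`) and `units`
#'   (per-precursor breakdown).
#' @export
family_representation <- function(locations, predicted) {
  found <- dplyr::filter(locations, .data$found)
  n_loci <- found |>
    dplyr::count(.data$precursor_id, .data$family, name = "loci")
  matures <- predicted |>
    dplyr::distinct(.data$precursor, .data$mature) |>
    dplyr::count(.data$precursor, name = "n_matures")
  pre_seq <- predicted |>
    dplyr::distinct(.data$assigned_name, .data$precursor)
  units <- n_loci |>
    dplyr::left_join(pre_seq, by = c(precursor_id = "assigned_name")) |>
    dplyr::left_join(matures, by = "precursor") |>
    dplyr::mutate(n_matures = dplyr::coalesce(.data$n_matures, 1L),
                  units = .data$loci +
                    ifelse(.data$loci == 1L, .data$n_matures - 1L, 0L))
  family_counts <- units |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(count = sum(.data$units), .groups = "drop") |>
    dplyr::arrange(.data$family)
  contig_families <- found |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      families = paste(sort(unique(.data$family)), collapse = ","),
      .groups = "drop")
  list(family_counts = family_counts, contig_families = contig_families,
       units = dplyr::select(units, "precursor_id", "family", "loci",
                             "n_matures", "units"))
}
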