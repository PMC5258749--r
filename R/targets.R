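#' Read a psRNATarget-dialect prediction table
#'
#' Tab-separated with a header naming at least `miRNA_Acc`, `Target_Acc`,
#' `Expectation` and `UPE`; `Inhibition` and `Multiplicity` are optional
#' and unknown extra columns are ignored. Rows whose numeric fields fail to
#' parse are dropped with a warning.
#'
#' @param path Path to the table.
#' @return Tibble `mirna_name`, `target_id`, `expectation`, `upe`,
#'   `inhibition_mode`, `multiplicity`.
#' @export
read_psrnatarget <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("miRNA_Acc", "Target_Acc", "Expectation", "UPE")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    mirna_name = tab$miRNA_Acc,
    target_id = tab$Target_Acc,
    expectation = suppressWarnings(as.numeric(tab$Expectation)),
    upe = suppressWarnings(as.numeric(tab$UPE)),
    inhibition_mode = if ("Inhibition" %in% names(tab)) tab$Inhibition
                      else NA_character_,
    multiplicity = if ("Multiplicity" %in% names(tab))
      suppressWarnings(as.integer(tab$Multiplicity)) else 1L
  )
  bad <- is.na(out$expectation) | is.na(out$upe)
  if (any(bad)) {
    warning("skipping ", sum(bad), " row(s) with malformed numeric fields",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Write a target table in the psRNATarget dialect
#'
#' Companion writer used by fixtures and round-trip tests.
#'
#' @param rows Tibble as returned by [read_psrnatarget()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psrnatarget <- function(rows, path) {
  tab <- tibble::tibble(
    miRNA_Acc = rows$mirna_name, Target_Acc = rows$target_id,
    Expectation = rows$expectation, UPE = rows$upe,
    Inhibition = rows$inhibition_mode, Multiplicity = rows$multiplicity)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Most significant annotated target per miRNA
#'
#' For each miRNA, candidate targets are those with a known functional
#' annotation (annotation present and not matching the uncharacterized
#' patterns). The winner minimizes `upe + expectation`; ties go to the
#' target whose exact annotation string is most frequent across the whole
#' annotated table, then to the lexicographically smallest target id.
#' miRNAs with no annotated target are reported with `NA` enrichment.
#'
#' @param rows Target rows from [read_psrnatarget()].
#' @param annotations Tibble `target_id`, `annotation` mapping targets to
#'   functional annotations.
#' @param exclude_patterns Case-insensitive substrings marking
#'   uncharacterized annotations (default `"uncharacterized"`,
#'   `"hypothetical"`, `"predicted protein"`, `"unknown"`).
#' @return One row per miRNA: `mirna_name`, `target_id`, `score`
#'   (`upe + expectation`), `annotation` (`NA` when no annotated target).
#' @export
#' @examples
#' rows <- tibble::tibble(mirna_name = "miR1", target_id = c("A", "B"),
#'                        expectation = c(2, 3), upe = c(10, 5),
#'                        inhibition_mode = "cleavage", multiplicity = 1L)
#' ann <- tibble::tibble(target_id = c("A", "B"),
#'                       annotation = c("kinase", "transporter"))
#' enrich_targets(rows, ann)
enrich_targets <- function(rows, annotations,
                           exclude_patterns = c("uncharacterized",
                                                "hypothetical",
                                                "predicted protein",
                                                "unknown")) {
  ann <- dplyr::distinct(annotations, .data$target_id, .keep_all = TRUE)
  joined <- dplyr::left_join(rows, ann, by = "target_id")
  uncharacterized <- function(a) {
    is.na(a) | !nzchar(a) |
      Reduce(`|`, lapply(exclude_patterns, function(p)
        stringr::str_detect(stringr::str_to_lower(a), stringr::fixed(p))))
  }
  annotated <- dplyr::filter(joined, !uncharacterized(.data$annotation))
  abundance <- dplyr::count(annotated, .data$annotation, name = "abundance")
  winners <- annotated |>
    dplyr::mutate(score = .data$upe + .data$expectation) |>
    dplyr::left_join(abundance, by = "annotation") |>
    dplyr::group_by(.data$mirna_name) |>
    dplyr::arrange(.data$score, dplyr::desc(.data$abundance),
                   .data$target_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("mirna_name", "target_id", "score", "annotation")
  all_mirnas <- tibble::tibble(mirna_name = unique(rows$mirna_name))
  dplyr::left_join(all_mirnas, winners, by = "mirna_name") |>
    dplyr::arrange(.data$mirna_name)
}
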