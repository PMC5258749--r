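#' Judge precursor candidates against the qualification criteria
#'
#' Applies the three structural criteria plus the N screen, one verdict
#' label per candidate:
#' * `Multiloop` - two or more helices branch between the mature and the
#'   hairpin tip (a single linear stem-loop above the mature is legal);
#' * `Head` - mature or star extends into the terminal (head) loop;
#' * `Dicer-cut` - a duplex mismatch at the Dicer cut regions (the first
#'   and last `dicer_margin` duplex positions of mature or star);
#' * `N-in-mature` - the mature sequence contains `N`;
#' * `OK` - all criteria pass.
#' When several criteria fail, the first structural defect in the order
#' above is reported.
#'
#' @param candidates Tibble from [fold_hairpins()]; rejected rows keep
#'   their rejection reason and receive no verdict.
#' @param dicer_margin Number of duplex-end positions checked on each side
#'   (default 2). Values other than 2 re-derive the end mismatches from the
#'   stored fold.
#' @return The input with a `verdict` column added and an `index` column
#'   numbering the rows (the back-reference used by downstream outputs).
#' @export
judge_candidates <- function(candidates, dicer_margin = 2L) {
  out <- dplyr::mutate(candidates, index = dplyr::row_number())
  if (nrow(out) == 0L) return(dplyr::mutate(out, verdict = character(0)))
  end_mm <- if (dicer_margin == 2L) {
    out$dicer_end_mismatches
  } else {
    purrr::pmap_int(out, function(...) {
      r <- list(...)
      if (!identical(r$status, "ok")) return(NA_integer_)
      a <- assess_duplex(r$fold[[1]], r$mature_start, r$mature_end)
      p <- r$fold[[1]]$pair_of
      dpos <- function(iv) head(iv, -2L)
      cnt <- function(iv, lo, hi) {
        dp <- dpos(iv)
        ends <- unique(c(head(dp, dicer_margin), utils::tail(dp, dicer_margin)))
        q <- p[ends]
        sum(q == 0 | q < lo | q > hi)
      }
      cnt(r$mature_start:r$mature_end, r$star_start, r$star_end) +
        cnt(r$star_start:r$star_end, r$mature_start, r$mature_end)
    })
  }
  dplyr::mutate(out,
    verdict = dplyr::case_when(
      status != "ok"                       ~ NA_character_,
      branch_count_above >= 2L             ~ "Multiloop",
      head_overlap                         ~ "Head",
      end_mm > 0L                          ~ "Dicer-cut",
      stringr::str_detect(mature, "N")     ~ "N-in-mature",
      TRUE                                 ~ "OK"
    ))
}

#' Resolve redundant annotations of the same mature sequence
#'
#' Several references may hit the same mature at the same locus with
#' different mismatch sets; the annotation with the fewest mismatches to
#' its reference wins. Exact ties keep all tied homolog ids, comma-joined,
#' for the user (or [tiebreak_by_precursor()]) to resolve.
#'
#' @param judged Tibble from [judge_candidates()], already filtered to the
#'   rows to consider (normally `verdict == "OK"`).
#' @return One row per (contig, precursor location, mature) with
#'   `homolog_ids` (comma-joined on ties), `star_list` (semicolon-joined
#'   distinct stars) and the winning row's columns.
#' @export
resolve_redundancy <- function(judged) {
  judged |>
    dplyr::group_by(.data$contig_id, .data$strand,
                    .data$precursor_contig_start, .data$precursor_contig_end,
                    .data$mature) |>
    dplyr::group_modify(function(g, key) {
      best <- g[g$ref_mismatches == min(g$ref_mismatches), , drop = FALSE]
      ids <- sort(unique(best$ref_id))
      first <- best[order(best$ref_id), ][1, ]
      first$homolog_ids <- paste(ids, collapse = ",")
      first$star_list <- paste(unique(g$star), collapse = ";")
      first
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$index)
}

#' Resolve a comma-joined annotation by precursor similarity
#'
#' When a mature is equally similar to references from several families,
#' the family whose *precursor* aligns best to the newly identified
#' precursor is picked (best ungapped match score; remaining ties go to the
#' lexicographically smallest family).
#'
#' @param drafts Tibble from [resolve_redundancy()] (needs `homolog_ids`
#'   and `precursor`).
#' @param ref_precursors Reference precursor tibble (`id`, `residues`)
#'   with miRBase-style ids; may be `NULL`, in which case drafts are
#'   returned unchanged.
#' @return `drafts` with multi-family `homolog_ids` reduced to the winning
#'   family's id(s) where reference precursors allow it.
#' @export
tiebreak_by_precursor <- function(drafts, ref_precursors = NULL) {
  if (is.null(ref_precursors) || nrow(drafts) == 0L) return(drafts)
  ref_fam <- parse_mirna_id(ref_precursors$id)$family
  score <- function(query, subject) {
    h <- ungapped_hits_cpp(as_rna(query), as_rna(subject), 10L, 0)
    if (nrow(h) == 0L) 0L else max(h$matches)
  }
  drafts |>
    dplyr::rowwise() |>
    dplyr::mutate(homolog_ids = {
      ids <- strsplit(.data$homolog_ids, ",", fixed = TRUE)[[1]]
      fams <- parse_mirna_id(ids)$family
      if (length(unique(fams)) < 2L) .data$homolog_ids else {
        sc <- vapply(unique(fams), function(fam) {
          subj <- ref_precursors$residues[ref_fam == fam]
          if (length(subj) == 0L) return(-1L)
          max(vapply(subj, function(s) score(.data$precursor, s), integer(1)))
        }, integer(1))
        if (all(sc < 0L)) .data$homolog_ids else {
          win <- sort(names(sc)[sc == max(sc)])[1]
          paste(ids[fams == win], collapse = ",")
        }
      }
    }) |>
    dplyr::ungroup()
}

#' Predict and name miRNAs from judged candidates
#'
#' Keeps qualifying candidates (`verdict == "OK"`), optionally excluding
#' suspects (zero-mismatch duplexes, routed to a separate stream by
#' default), resolves redundant annotations, applies the naming rules of
#' [assign_mirna_name()] and makes names unique by numbering family members
#' `-1, -2, ...` in discovery order.
#'
#' @param judged Tibble from [judge_candidates()].
#' @param ref_precursors Optional reference precursor tibble for
#'   [tiebreak_by_precursor()].
#' @param include_suspects Keep suspect candidates in the main list
#'   (default `FALSE`).
#' @return A tibble of predicted miRNAs: `assigned_name`, `mature`,
#'   `star_list`, `precursor`, `homolog_ids`, `index`, `family`,
#'   `mature_arm`, location columns and energy statistics.
#' @export
predict_mirnas <- function(judged, ref_precursors = NULL,
                           include_suspects = FALSE) {
  ok <- dplyr::filter(judged, .data$verdict == "OK")
  if (!include_suspects) ok <- dplyr::filter(ok, !.data$suspect)
  if (nrow(ok) == 0L) {
    return(tibble::tibble(assigned_name = character(), family = character(),
                          mature = character(), star_list = character(),
                          precursor = character(), homolog_ids = character(),
                          index = integer()))
  }
  drafts <- resolve_redundancy(ok) |>
    tiebreak_by_precursor(ref_precursors)
  named <- drafts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      assigned_name = {
        ids <- strsplit(.data$homolog_ids, ",", fixed = TRUE)[[1]]
        nm <- unique(vapply(ids, assign_mirna_name,
                            detected_arm = .data$mature_arm, character(1)))
        paste(sort(nm), collapse = ",")
      },
      family = paste(sort(unique(parse_mirna_id(
        strsplit(.data$homolog_ids, ",", fixed = TRUE)[[1]])$family)),
        collapse = ",")
    ) |>
    dplyr::ungroup()
  # distinct-suffix uniqueness: number repeated names in discovery order
  named |>
    dplyr::group_by(.data$assigned_name) |>
    dplyr::mutate(.n_in_name = dplyr::n(),
                  .k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(assigned_name = ifelse(.data$.n_in_name > 1L,
                                         paste0(.data$assigned_name, "-", .data$.k),
                                         .data$assigned_name)) |>
    dplyr::select(-".n_in_name", -".k") |>
    dplyr::relocate("assigned_name", "family", "mature", "star_list",
                    "precursor", "homolog_ids", "index")
}
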