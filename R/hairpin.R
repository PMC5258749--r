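#' Build the folding window around a homology hit
#'
#' Extracts the window reaching `window_len / 2` nt beyond each end of the
#' hit, clipped at the contig edges, so the hit sits at the window midpoint
#' whenever no clipping occurs. Antisense hits are windowed on the reverse
#' complement so that the mature miRNA always reads 5'->3' in window
#' coordinates.
#'
#' @param hit One row of the tibble from [scan_mirna_hits()] (as a list or
#'   one-row tibble).
#' @param contig_residues Residues of the hit's contig (forward strand).
#' @param window_len Target window length (default 700); must be at least
#'   four times the hit length.
#' @return A list with `residues` (RNA, window sequence 5'->3' on the hit's
#'   strand), `window_start`, `window_end` (forward-strand contig
#'   coordinates) and `mature_start`, `mature_end` (1-based within the
#'   window).
#' @export
build_window <- function(hit, contig_residues, window_len = 700L) {
  m <- hit$end - hit$start + 1L
  if (window_len < 4L * m) {
    stop("window_len must be at least 4x the hit length", call. = FALSE)
  }
  L <- nchar(contig_residues)
  half <- window_len %/% 2L
  ws <- max(1L, hit$start - half)
  we <- min(L, hit$end + half)
  fwd <- as_rna(substr(contig_residues, ws, we))
  if (identical(hit$strand, "antisense")) {
    res <- revcomp(fwd)
    ms <- we - hit$end + 1L
  } else {
    res <- fwd
    ms <- hit$start - ws + 1L
  }
  list(residues = res, window_start = ws, window_end = we,
       mature_start = ms, mature_end = ms + m - 1L)
}

# Duplex bookkeeping for a mature placed on a folded sequence.
#
# The star interval is derived from the pairing partners of the mature
# positions shifted +2 (the canonical 2-nt 3' overhang of a Dicer duplex).
# Because of those staggered overhangs, the 3'-terminal 2 nt of mature and
# of star pair outside their partner by construction, so they are exempt
# from mismatch counting; a "duplex mismatch" is a non-exempt position that
# is unpaired or paired outside the partner interval. G.U wobble is a pair.
assess_duplex <- function(fold, mature_start, mature_end,
                          min_paired_frac = 0.6) {
  p <- fold$pair_of
  n <- length(p)
  mat <- mature_start:mature_end
  partners <- p[mat]
  outside <- partners > 0 & (partners < mature_start | partners > mature_end)
  if (mean(outside) < min_paired_frac) {
    return(list(status = "rejected", reason = "unstructured-mature"))
  }
  geo <- hairpin_geometry(fold, mature_start, mature_end)
  arm <- geo$anchor_arm
  if (is.na(arm)) {
    return(list(status = "rejected", reason = "unstructured-mature"))
  }
  pp <- partners[outside]
  star_start <- max(1L, min(pp) + 2L)
  star_end <- min(n, max(pp) + 2L)
  star <- star_start:star_end

  duplex_positions <- function(iv) head(iv, -2L) # exempt the 3' overhang
  mism <- function(iv, partner_lo, partner_hi) {
    q <- p[duplex_positions(iv)]
    sum(q == 0 | q < partner_lo | q > partner_hi)
  }
  mature_mm <- mism(mat, star_start, star_end)
  star_mm <- mism(star, mature_start, mature_end)
  end_mm <- function(iv, partner_lo, partner_hi, margin = 2L) {
    dp <- duplex_positions(iv)
    ends <- unique(c(head(dp, margin), utils::tail(dp, margin)))
    q <- p[ends]
    sum(q == 0 | q < partner_lo | q > partner_hi)
  }
  list(status = "ok",
       mature_start = mature_start, mature_end = mature_end,
       star_start = star_start, star_end = star_end,
       mature_arm = arm,
       duplex_mismatches = mature_mm,
       star_mismatches = star_mm,
       dicer_end_mismatches = end_mm(mat, star_start, star_end) +
         end_mm(star, mature_start, mature_end),
       suspect = mature_mm == 0L,
       branch_count_above = geo$branch_count_above,
       terminal_loop = geo$terminal_loop,
       head_overlap = {
         tl <- geo$terminal_loop
         !is.null(tl) && (any(mat >= tl[1] & mat <= tl[2]) ||
                          any(star >= tl[1] & star <= tl[2]))
       })
}

#' Excise and refold the precursor around a duplex
#'
#' The precursor spans from 20 nt outside the near end of the mature to
#' 20 nt outside the far end of the star (clipped at window edges), is
#' refolded, and the duplex is re-assessed on the refolded structure. If
#' the refolded structure no longer holds the mature:star pairing the
#' candidate is rejected with reason `"refold-lost-duplex"`.
#'
#' @param window_residues RNA window sequence.
#' @param duplex Assessment list from the window fold (mature/star
#'   intervals in window coordinates).
#' @param flank Flank length beyond each duplex end (default 20).
#' @return A list with `status`; on success also `precursor` (residues),
#'   `precursor_start` (offset of the precursor within the window), `fold`
#'   (refolded `sumir_fold`) and the precursor-local duplex assessment.
#' @export
excise_precursor <- function(window_residues, duplex, flank = 20L) {
  lo <- max(1L, min(duplex$mature_start, duplex$star_start) - flank)
  hi <- min(nchar(window_residues),
            max(duplex$mature_end, duplex$star_end) + flank)
  pre <- substr(window_residues, lo, hi)
  f <- fold_rna(pre)
  local <- assess_duplex(f, duplex$mature_start - lo + 1L,
                         duplex$mature_end - lo + 1L)
  if (local$status != "ok") {
    return(list(status = "rejected", reason = "refold-lost-duplex"))
  }
  c(list(status = "ok", precursor = pre, precursor_start = lo, fold = f),
    local[setdiff(names(local), "status")])
}

#' Folding-energy statistics of a precursor
#'
#' @param mfe Minimum free energy in kcal/mol (negative for stable folds).
#' @param residues Precursor residues.
#' @return A one-row tibble: `length`, `mfe`, `amfe` (MFE per 100 nt),
#'   `gc_fraction` (over non-N residues) and `mfei` (|AMFE| / GC%,
#'   reported as a positive magnitude; `NA` when GC is zero).
#' @export
#' @examples
#' precursor_stats(-60, strrep("GCAU", 30))
precursor_stats <- function(mfe, residues) {
  n <- nchar(residues)
  non_n <- n - stringr::str_count(residues, "N")
  gc <- if (non_n == 0) 0 else stringr::str_count(residues, "[GC]") / non_n
  amfe <- mfe / n * 100
  tibble::tibble(length = n, mfe = mfe, amfe = amfe, gc_fraction = gc,
                 mfei = if (gc > 0) abs(amfe) / (gc * 100) else NA_real_)
}

#' Fold homology hits into precursor candidates
#'
#' The window stage of the pipeline: for each hit (deduplicated by contig,
#' window, strand and reference) the ~`window_len` nt window is folded, the
#' mature:star duplex located and pre-screened, the precursor excised and
#' refolded, and MFE/AMFE/MFEI statistics computed. Candidates whose mature
#' region is unstructured, or whose refold loses the duplex, are retained
#' as rejected rows with a reason. Zero-mismatch duplexes are flagged
#' `suspect` (possible inverted repeats / siRNAs) and are meant to be
#' processed as a separate stream.
#'
#' @param hits Tibble from [scan_mirna_hits()].
#' @param contigs The contig tibble the hits refer to.
#' @param window_len Folding window length (default 700).
#' @param flank Excision flank beyond the duplex ends (default 20).
#' @return A tibble with one row per candidate: hit columns, `status`,
#'   `reason`, `mature`, `star`, `precursor` sequences and the precursor's
#'   dot-bracket `structure`, precursor-local
#'   `mature_start`/`mature_end`/`star_start`/`star_end`, `mature_arm`,
#'   `duplex_mismatches`, `dicer_end_mismatches`, `branch_count_above`,
#'   `head_overlap`, `suspect`, `precursor_location` (forward-strand contig
#'   coordinates of the precursor), the energy statistics of
#'   [precursor_stats()] and a `fold` list-column with the refolded
#'   precursor.
#' @export
fold_hairpins <- function(hits, contigs, window_len = 700L, flank = 20L) {
  res_by_id <- setNames(contigs$residues, contigs$id)
  wins <- purrr::pmap(hits, function(...) {
    hit <- list(...)
    w <- build_window(hit, res_by_id[[hit$contig_id]], window_len)
    c(hit[c("contig_id", "strand", "ref_id", "mismatches", "mature")],
      list(hit_start = hit$start, hit_end = hit$end), w)
  })
  # one window per (contig, window, strand, ref)
  key <- vapply(wins, function(w)
    paste(w$contig_id, w$window_start, w$window_end, w$strand, w$ref_id,
          w$mature_start, sep = "\r"), character(1))
  wins <- wins[!duplicated(key)]

  rows <- purrr::map(wins, function(w) {
    base <- tibble::tibble(
      contig_id = w$contig_id, strand = w$strand, ref_id = w$ref_id,
      hit_start = w$hit_start, hit_end = w$hit_end,
      ref_mismatches = w$mismatches, mature = w$mature,
      window_start = w$window_start, window_end = w$window_end)
    f <- fold_rna(w$residues)
    a <- assess_duplex(f, w$mature_start, w$mature_end)
    if (a$status != "ok") {
      return(dplyr::mutate(base, status = "rejected", reason = a$reason))
    }
    ex <- excise_precursor(w$residues, a, flank)
    if (ex$status != "ok") {
      return(dplyr::mutate(base, status = "rejected", reason = ex$reason))
    }
    st <- precursor_stats(ex$fold$mfe, ex$precursor)
    # precursor coordinates back on the forward strand of the contig
    plen <- nchar(ex$precursor)
    if (w$strand == "sense") {
      ps <- w$window_start + ex$precursor_start - 1L
    } else {
      ps <- w$window_end - (ex$precursor_start + plen - 1L) + 1L
    }
    dplyr::mutate(base,
      status = "ok", reason = NA_character_,
      precursor = ex$precursor,
      structure = dot_bracket(ex$fold),
      precursor_contig_start = ps, precursor_contig_end = ps + plen - 1L,
      mature_start = ex$mature_start, mature_end = ex$mature_end,
      star_start = ex$star_start, star_end = ex$star_end,
      star = substr(ex$precursor, ex$star_start, ex$star_end),
      mature_arm = ex$mature_arm,
      duplex_mismatches = ex$duplex_mismatches,
      star_mismatches = ex$star_mismatches,
      dicer_end_mismatches = ex$dicer_end_mismatches,
      branch_count_above = ex$branch_count_above,
      head_overlap = ex$head_overlap,
      suspect = ex$suspect,
      length = st$length, mfe = st$mfe, amfe = st$amfe,
      gc_fraction = st$gc_fraction, mfei = st$mfei,
      fold = list(ex$fold))
  })
  dplyr::bind_rows(rows)
}
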