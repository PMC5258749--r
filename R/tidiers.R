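#' Tidy a pipeline run
#'
#' Returns the predicted miRNA table (one row per prediction) without
#' list-columns, ready for joining and plotting.
#'
#' @param x A `sumir_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sumir_run <- function(x, ...) {
  drop_list_cols(x$predicted)
}

#' One-row summary of a pipeline run
#'
#' Stage counts plus precursor length/MFE/MFEI summaries of the accepted
#' predictions.
#'
#' @param x A `sumir_run` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sumir_run <- function(x, ...) {
  p <- x$predicted
  stat <- function(v, f) if (nrow(p) == 0L) NA_real_ else f(v)
  dplyr::bind_cols(
    x$summary,
    tibble::tibble(
      mean_mature_len = stat(nchar(p$mature), mean),
      mean_precursor_len = stat(p$length, mean),
      median_precursor_len = stat(p$length, stats::median),
      sd_precursor_len = stat(p$length, stats::sd),
      mean_mfe = stat(p$mfe, mean),
      median_mfe = stat(p$mfe, stats::median),
      sd_mfe = stat(p$mfe, stats::sd),
      mean_mfei = stat(p$mfei, function(v) mean(v, na.rm = TRUE)),
      median_mfei = stat(p$mfei, function(v) stats::median(v, na.rm = TRUE)),
      sd_mfei = stat(p$mfei, function(v) stats::sd(v, na.rm = TRUE))
    ))
}

#' Tidy a fold into a per-position tibble
#'
#' @param x A `sumir_fold` object.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `partner`, `paired`.
#' @export
tidy.sumir_fold <- function(x, ...) {
  tibble::tibble(position = seq_len(nchar(x$residues)),
                 base = strsplit(x$residues, "", fixed = TRUE)[[1]],
                 partner = x$pair_of,
                 paired = x$pair_of > 0L)
}

#' One-row summary of a fold
#' @param x A `sumir_fold` object.
#' @param ... Unused.
#' @return Tibble with `length`, `mfe`, `n_pairs`, `backend`.
#' @export
glance.sumir_fold <- function(x, ...) {
  tibble::tibble(length = nchar(x$residues), mfe = x$mfe,
                 n_pairs = sum(x$pair_of > 0L) %/% 2L,
                 backend = x$backend)
}
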