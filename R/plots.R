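#' Arc diagram of a folded RNA
#'
#' Draws the sequence as a line with one arc per base pair; a quick visual
#' check that a candidate folds into a clean hairpin.
#'
#' @param object A `sumir_fold` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sumir_fold <- function(object, ...) {
  p <- object$pair_of
  i <- which(p > seq_along(p))
  arcs <- if (length(i)) {
    purrr::map_dfr(i, function(k) {
      j <- p[k]
      t <- seq(0, pi, length.out = 40)
      tibble::tibble(pair = k,
                     x = (k + j) / 2 + (j - k) / 2 * cos(t),
                     y = (j - k) / 2 * sin(t))
    })
  } else {
    tibble::tibble(pair = integer(), x = numeric(), y = numeric())
  }
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$pair)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "steelblue") +
    ggplot2::annotate("segment", x = 1, xend = length(p), y = 0, yend = 0) +
    ggplot2::labs(x = "position (nt)", y = NULL,
                  title = sprintf("MFE %.2f kcal/mol", object$mfe)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Stage-count funnel of a pipeline run
#'
#' @param object A `sumir_run` object.
#' @param ... Unused.
#' @return A ggplot bar chart of hits, hairpins (+suspects), predictions.
#' @export
autoplot.sumir_run <- function(object, ...) {
  s <- object$summary
  d <- tibble::tibble(
    stage = factor(c("hits", "hairpins", "suspects", "predicted"),
                   levels = c("hits", "hairpins", "suspects", "predicted")),
    count = c(s$find_hits, s$fold_hairpins, s$suspects, s$predicted_mirnas))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "candidates") +
    ggplot2::theme_minimal()
}

#' Family representation bar chart
#'
#' @param representation Output of [family_representation()] (or a
#'   `sumir_run`, whose representation is used).
#' @return A ggplot object.
#' @export
plot_representation <- function(representation) {
  if (inherits(representation, "sumir_run")) {
    representation <- representation$representation
  }
  d <- representation$family_counts
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$family,
                                                     .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "representation units") +
    ggplot2::theme_minimal()
}

#' Precursor MFE/MFEI distributions
#'
#' @param candidates Candidate tibble from [fold_hairpins()] (accepted
#'   rows are used) or the `judged` table of a `sumir_run`.
#' @return A ggplot object with MFE and MFEI histograms.
#' @export
plot_precursor_stats <- function(candidates) {
  if (inherits(candidates, "sumir_run")) candidates <- candidates$judged
  ok <- dplyr::filter(candidates, .data$status == "ok")
  d <- tidyr::pivot_longer(ok[, c("mfe", "mfei")],
                           dplyr::everything(),
                           names_to = "stat", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::labs(x = NULL, y = "precursors") +
    ggplot2::theme_minimal()
}
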