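#' Hairpin geometry relative to an anchor
#'
#' Classifies each position of a folded window relative to the hairpin that
#' holds the anchor (typically the mature miRNA): which arm it lies on, the
#' terminal ("head") loop, and how many helices branch from loops between
#' the anchor and the hairpin tip. A clean stem-loop above the anchor gives
#' `branch_count_above = 0`; a multibranched loop contributes all of its
#' helices.
#'
#' @param fold A `sumir_fold` object.
#' @param anchor_start,anchor_end 1-based closed interval of the anchor
#'   within the window.
#' @return A list with `arm` (character vector over positions: `"5p"`,
#'   `"3p"`, `"loop"`, `"exterior"`), `terminal_loop` (`c(start, end)` or
#'   `NULL`), `branch_count_above` (integer) and `anchor_arm` (`"5p"`,
#'   `"3p"` or `NA` when the anchor is entirely exterior).
#' @export
hairpin_geometry <- function(fold, anchor_start, anchor_end) {
  p <- fold$pair_of
  n <- length(p)
  stopifnot(anchor_start >= 1L, anchor_end <= n, anchor_start <= anchor_end)
  anchor <- anchor_start:anchor_end
  ap <- anchor[p[anchor] > 0]

  # region "above" the anchor: between its innermost paired position and
  # that position's partner
  if (length(ap) == 0L) {
    arm <- rep("exterior", n)
    return(list(arm = arm, terminal_loop = NULL,
                branch_count_above = 0L, anchor_arm = NA_character_))
  }
  amin <- min(ap); amax <- max(ap)
  if (p[amax] > amax) {
    lo <- amax + 1L; hi <- p[amax] - 1L       # anchor on the 5' side
  } else if (p[amin] < amin) {
    lo <- p[amin] + 1L; hi <- amin - 1L       # anchor on the 3' side
  } else {
    # anchor spans the head: innermost enclosed region
    inner <- ap[p[ap] > ap]
    x <- max(inner)
    lo <- x + 1L; hi <- p[x] - 1L
  }

  branches <- 0L
  terminal_loop <- NULL
  while (TRUE) {
    if (lo > hi) { terminal_loop <- NULL; break }
    helices <- list()
    k <- lo
    while (k <= hi) {
      if (p[k] > k && p[k] <= hi) { helices <- c(helices, list(c(k, p[k]))); k <- p[k] + 1L }
      else k <- k + 1L
    }
    if (length(helices) == 0L) { terminal_loop <- c(lo, hi); break }
    if (length(helices) > 1L) branches <- branches + length(helices)
    # descend the leftmost helix (the only one when unbranched)
    lo <- helices[[1]][1] + 1L
    hi <- helices[[1]][2] - 1L
  }

  # exterior = not enclosed by any pair
  depth <- integer(n); d <- 0L
  for (k in seq_len(n)) {
    if (p[k] > k) { depth[k] <- d + 1L; d <- d + 1L }
    else if (p[k] > 0) { depth[k] <- d; d <- d - 1L }
    else depth[k] <- d
  }
  arm <- rep(NA_character_, n)
  if (is.null(terminal_loop)) {
    t1 <- lo; t2 <- hi # degenerate (empty) head between lo/hi bounds
  } else {
    t1 <- terminal_loop[1]; t2 <- terminal_loop[2]
  }
  arm[seq_len(n) < t1] <- "5p"
  arm[seq_len(n) > t2] <- "3p"
  if (!is.null(terminal_loop)) arm[t1:t2] <- "loop"
  arm[depth == 0L & p == 0L] <- "exterior"

  a_arm <- arm[anchor]
  a_arm <- a_arm[a_arm %in% c("5p", "3p")]
  anchor_arm <- if (length(a_arm) == 0L) NA_character_ else
    names(sort(table(a_arm), decreasing = TRUE))[1]

  list(arm = arm, terminal_loop = terminal_loop,
       branch_count_above = branches, anchor_arm = anchor_arm)
}
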