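#' Energy parameters of the built-in folding model
#'
#' The built-in engine scores pseudoknot-free secondary structures with a
#' simplified nearest-neighbour model: stacking energies for the 36 ordered
#' pair stacks (canonical pairs plus G.U wobble), a linear hairpin-loop
#' penalty, a linear internal/bulge-loop penalty capped at 30 unpaired
#' bases, and a linear multibranch penalty. All values are integers in
#' 1/100 kcal/mol so that minima compare exactly; signs follow the usual
#' convention (stabilizing stacks are negative).
#'
#' @return A named list: `stack` (6x6 integer matrix, pair order
#'   AU, CG, GC, UA, GU, UG; `stack[a, b]` is the energy of inner pair `b`
#'   stacked under outer pair `a`), `hairpin_base`, `hairpin_slope`
#'   (per unpaired base beyond the 3-base minimum), `internal_base`,
#'   `internal_slope` (per unpaired base), `ml_close`, `ml_branch`,
#'   `ml_unpaired` (multibranch closing / per-branch / per-unpaired terms),
#'   `max_loop`, `min_hairpin`.
#' @export
fold_params <- function() {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU    CG    GC    UA    GU    UG      outer:
            -  90, -220, -210, -110, - 60, -140,  # AU
            - 210, -330, -240, -210, -140, -210,  # CG
            - 240, -340, -330, -220, -150, -250,  # GC
            - 130, -240, -210, - 90, -100, -130,  # UA
            - 130, -250, -210, -140, - 50,  130,  # GU
            - 100, -150, -140, - 60,   30, - 50   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  storage.mode(stack) <- "integer"
  list(stack = stack,
       hairpin_base = 500L, hairpin_slope = 11L,
       internal_base = 200L, internal_slope = 35L,
       ml_close = 340L, ml_branch = 40L, ml_unpaired = 10L,
       max_loop = 30L, min_hairpin = 3L)
}

#' Fold an RNA sequence into its minimum-free-energy structure
#'
#' Computes the pseudoknot-free secondary structure of minimum free energy
#' under the model of [fold_params()] with a Zuker-style dynamic program.
#' Only `{AU, UA, GC, CG, GU, UG}` pairs form; `N` never pairs; hairpin
#' loops hold at least 3 unpaired bases. The result is deterministic: among
#' co-optimal structures a fixed backtracking order is used (hairpin before
#' the innermost-leftmost interior pair before the leftmost multibranch
#' split), so identical input always yields the identical pair table.
#'
#' @param residues A single RNA string (`A C G U N`; `T` is converted to
#'   `U`), length at least 10.
#' @return An object of class `sumir_fold`: a list with `residues`,
#'   `pair_of` (integer vector, partner index per position, 0 = unpaired),
#'   `mfe` (kcal/mol), `backend` (`"builtin"`).
#' @seealso [dot_bracket()], [structure_energy()], [hairpin_geometry()]
#' @export
#' @examples
#' fold_rna("GGGAAAACCC")
fold_rna <- function(residues) {
  stopifnot(length(residues) == 1L)
  residues <- as_rna(residues)
  if (nchar(residues) < 10L) {
    stop("fold_rna() needs at least 10 nt, got ", nchar(residues),
         call. = FALSE)
  }
  if (grepl("[^ACGUN]", residues)) {
    stop("fold_rna() alphabet is {A,C,G,U,N}", call. = FALSE)
  }
  p <- fold_params()
  res <- fold_engine_cpp(residues, p$stack, p$hairpin_base, p$hairpin_slope,
                         p$internal_base, p$internal_slope,
                         p$ml_close, p$ml_branch, p$ml_unpaired,
                         p$max_loop, p$min_hairpin)
  structure(list(residues = residues,
                 pair_of = as.integer(res$pair),
                 mfe = res$energy / 100,
                 backend = "builtin"),
            class = "sumir_fold")
}

#' @export
print.sumir_fold <- function(x, ...) {
  cat("<sumir_fold> ", nchar(x$residues), " nt, MFE ",
      sprintf("%.2f", x$mfe), " kcal/mol (", x$backend, ")\n", sep = "")
  cat(x$residues, "\n", dot_bracket(x), "\n", sep = "")
  invisible(x)
}

#' Dot-bracket (Vienna) notation for a fold
#' @param fold A `sumir_fold` object or a pair vector.
#' @return A dot-bracket string.
#' @export
dot_bracket <- function(fold) {
  p <- if (inherits(fold, "sumir_fold")) fold$pair_of else as.integer(fold)
  out <- rep(".", length(p))
  out[p > seq_along(p)] <- "("
  out[p > 0 & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

#' Parse dot-bracket notation into a pair vector
#' @param db A dot-bracket string using `(`, `)` and `.`.
#' @return Integer pair vector (0 = unpaired).
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  p
}

#' Evaluate the energy of a given structure
#'
#' Independent structure-energy evaluator: decomposes an explicit pair
#' table into hairpin, stack, internal/bulge and multibranch loops and sums
#' their energies under [fold_params()]. Shares only the parameter table
#' with the folding engine, not its dynamic program, so it can audit
#' [fold_rna()] results and score enumerated structures.
#'
#' @param residues RNA string.
#' @param pair_of Integer pair vector (partner index, 0 = unpaired); must
#'   be a valid pseudoknot-free structure with only canonical/wobble pairs.
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(residues, pair_of) {
  residues <- as_rna(residues)
  n <- nchar(residues)
  p <- as.integer(pair_of)
  stopifnot(length(p) == n)
  paired <- which(p > 0)
  if (!all(p[p[paired]] == paired)) {
    stop("pair table is not an involution", call. = FALSE)
  }
  par <- fold_params()
  pair_name <- function(i, j) {
    nm <- paste0(substr(residues, i, i), substr(residues, j, j))
    if (!nm %in% rownames(par$stack)) {
      stop("illegal pair ", nm, " at (", i, ",", j, ")", call. = FALSE)
    }
    nm
  }
  total <- 0L
  for (i in which(p > seq_len(n))) {
    j <- p[i]
    # children: top-level pairs strictly inside (i, j)
    kids_i <- integer(0); unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (p[k] > k) { kids_i <- c(kids_i, k); k <- p[k] + 1L }
      else if (p[k] == 0) { unpaired <- unpaired + 1L; k <- k + 1L }
      else stop("pseudoknot or malformed structure at position ", k,
                call. = FALSE)
    }
    nk <- length(kids_i)
    total <- total +
      if (nk == 0L) {
        if (unpaired < par$min_hairpin)
          stop("hairpin loop shorter than ", par$min_hairpin, call. = FALSE)
        par$hairpin_base + par$hairpin_slope * (unpaired - par$min_hairpin)
      } else if (nk == 1L) {
        if (unpaired == 0L)
          par$stack[pair_name(i, j), pair_name(kids_i, p[kids_i])]
        else if (unpaired > par$max_loop)
          Inf # internal/bulge loops beyond the cap are disallowed
        else
          par$internal_base + par$internal_slope * unpaired
      } else {
        par$ml_close + par$ml_branch * nk + par$ml_unpaired * unpaired
      }
  }
  total / 100
}
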