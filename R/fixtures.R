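# run code under a local RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_seq <- function(n, letters = c("A", "C", "G", "U"),
                     prob = c(0.26, 0.24, 0.24, 0.26)) {
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

# bases that pair x (canonical + wobble)
pairs_of <- function(x) {
  switch(x, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"), character(0))
}

#' Construct a synthetic miRNA precursor with known truth
#'
#' Builds a hairpin holding the mature on the requested arm with a
#' continuous designed stem, a 2-nt 3' tail, designed duplex mismatches
#' (substitutions on the star side at the partner positions, chosen to
#' break canonical and wobble pairing) and, optionally, one structural
#' defect: an inserted pair of branch helices above the mature
#' (`"multiloop"`), the mature shifted into the terminal loop (`"head"`),
#' or a substitution at a duplex end (`"dicer-cut"`). A defect-free spec
#' with at least one duplex mismatch is constructed to pass the
#' qualification criteria; a defect-free spec with no mismatches is a
#' "suspect" (perfect duplex) by construction.
#'
#' @param family Family token, e.g. `"miR156"`.
#' @param mature Mature sequence (RNA, 20-24 nt) or `NULL` to draw one.
#' @param mature_len Length of a drawn mature (default 21).
#' @param loop_len Terminal loop length (default 10, minimum 4).
#' @param duplex_mismatch_positions 1-based mature positions (within the
#'   duplex region, i.e. at most `mature_len - 2`) to make mismatches.
#' @param arm `"5p"` or `"3p"`.
#' @param defect One of `"none"`, `"multiloop"`, `"head"`, `"dicer-cut"`.
#' @param seed Integer seed; the construction is deterministic per seed.
#' @return A one-row tibble: `family`, `arm`, `defect`, `mature`, `star`
#'   (designed star sequence), `precursor`, `mature_start`, `mature_end`
#'   (within the precursor).
#' @export
make_precursor <- function(family, mature = NULL, mature_len = 21L,
                           loop_len = 10L,
                           duplex_mismatch_positions = integer(0),
                           arm = c("5p", "3p"),
                           defect = c("none", "multiloop", "head",
                                      "dicer-cut"),
                           seed = 1L) {
  arm <- match.arg(arm)
  defect <- match.arg(defect)
  if (loop_len < 4L) stop("loop_len must be at least 4", call. = FALSE)
  with_seed(seed, {
    if (is.null(mature)) mature <- rand_seq(mature_len)
    mature <- as_rna(mature)
    L <- nchar(mature)
    if (L < 20L || L > 24L) stop("mature must be 20-24 nt", call. = FALSE)
    if (defect == "dicer-cut") {
      duplex_mismatch_positions <- unique(c(1L, duplex_mismatch_positions))
    }
    if (any(duplex_mismatch_positions > L - 2L)) {
      stop("duplex mismatch positions must lie in the duplex region (<= ",
           L - 2L, ")", call. = FALSE)
    }
    ext <- rand_seq(5L, c("G", "C"), c(0.5, 0.5))
    loop <- rand_seq(loop_len, c("A", "C"), c(0.6, 0.4))
    tail2 <- rand_seq(2L, c("A", "C"), c(0.5, 0.5))
    mk_branch <- function() {
      g <- rand_seq(6L, c("G", "C"), c(0.5, 0.5))
      paste0(g, "ACA", revcomp(g))
    }
    break_pair <- function(stem_rc, partner_pos, mature_base) {
      # substitute the star-side base so it pairs neither canonically nor
      # by wobble with the mature base
      cur <- substr(stem_rc, partner_pos, partner_pos)
      choices <- setdiff(c("A", "C", "G", "U"),
                         c(pairs_of(mature_base), cur))
      substr(stem_rc, partner_pos, partner_pos) <- choices[1]
      stem_rc
    }
    if (defect == "head") {
      # mature's loop-proximal 2 nt sit in the terminal loop
      stem <- if (arm == "5p") substr(mature, 1L, L - 2L)
              else substr(mature, 3L, L)
      stem_rc <- revcomp(stem)
      Ls <- nchar(stem)
      for (pos in duplex_mismatch_positions) {
        sp <- if (arm == "5p") pos else pos - 2L
        if (sp < 1L || sp > Ls) next
        stem_rc <- break_pair(stem_rc, Ls - sp + 1L,
                              substr(stem, sp, sp))
      }
      if (arm == "5p") {
        # mature's last 2 nt fall inside the terminal loop
        pre <- paste0(mature, loop, stem_rc, tail2)
        ms <- 1L
      } else {
        # mature's first 2 nt fall inside the terminal loop
        pre <- paste0(stem_rc, loop, mature, tail2)
        ms <- Ls + loop_len + 1L
      }
      star <- stem_rc
    } else {
      # a basal stem below the duplex, as in genuine pre-miRNAs, anchors
      # the hairpin inside the larger folding window
      basal <- rand_seq(12L, prob = c(0.2, 0.3, 0.3, 0.2))
      stem <- if (arm == "5p") paste0(basal, mature, ext)
              else paste0(ext, mature, basal)
      stem_rc <- revcomp(stem)
      Ls <- nchar(stem)
      m_off <- if (arm == "5p") nchar(basal) else nchar(ext) # mature offset in stem
      for (pos in duplex_mismatch_positions) {
        sp <- m_off + pos
        stem_rc <- break_pair(stem_rc, Ls - sp + 1L, substr(stem, sp, sp))
      }
      mid <- if (defect == "multiloop") {
        paste0("AA", mk_branch(), "AA", mk_branch(), "AA")
      } else {
        loop
      }
      if (arm == "5p") {
        pre <- paste0(stem, mid, stem_rc, tail2)
        ms <- nchar(basal) + 1L
      } else {
        pre <- paste0(stem_rc, mid, stem, tail2)
        ms <- Ls + nchar(mid) + nchar(ext) + 1L
      }
      # designed star: partners of the mature, shifted +2 (3' overhang)
      total <- 2L * Ls + nchar(mid)
      m_end_in_pre <- ms + L - 1L
      p_lo <- total - m_end_in_pre + 1L
      p_hi <- total - ms + 1L
      star <- substr(pre, p_lo + 2L, min(nchar(pre), p_hi + 2L))
    }
    tibble::tibble(family = family, arm = arm, defect = defect,
                   mature = mature, star = star, precursor = pre,
                   mature_start = ms, mature_end = ms + L - 1L)
  })
}

#' Plant precursors and repeats into a synthetic genome
#'
#' Generates an i.i.d. background contig at the stated GC content and
#' inserts each precursor (and optional repeat/TE copies) at recorded,
#' non-overlapping loci on recorded strands. Contig residues are emitted in
#' the DNA alphabet, as sequenced genomes are.
#'
#' @param precursors Tibble from [make_precursor()] rows; optional columns
#'   `n_loci` (default 1) and `strand` (`"sense"`/`"antisense"`; default
#'   drawn at random per locus).
#' @param background_len Total background length in nt.
#' @param gc Background GC fraction (default 0.44, a typical grass genome).
#' @param te_inserts Optional tibble (`id`, `residues`) of repeat elements
#'   to insert once each.
#' @param seed Integer seed.
#' @param contig_id Contig name (default `"chr1"`).
#' @return A list: `contigs` (sequence tibble), `truth` (planted loci:
#'   `family`, `arm`, `mature`, `star`, `precursor`, `contig_id`, `start`,
#'   `end`, `strand`), `te_loci` (planted repeats, same shape).
#' @export
make_genome <- function(precursors, background_len = 100000L, gc = 0.44,
                        te_inserts = NULL, seed = 1L, contig_id = "chr1") {
  with_seed(seed, {
    inserts <- c(as_dna(precursors$precursor),
                 if (!is.null(te_inserts)) as_dna(te_inserts$residues))
    n_loci <- if ("n_loci" %in% names(precursors)) precursors$n_loci
              else rep(1L, nrow(precursors))
    copies <- c(rep(seq_len(nrow(precursors)), n_loci),
                if (!is.null(te_inserts))
                  nrow(precursors) + seq_len(nrow(te_inserts)))
    lens <- nchar(inserts)[copies]
    need <- sum(lens)
    if (background_len < need + 10L * length(lens)) {
      stop("background_len too short for the requested inserts",
           call. = FALSE)
    }
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bg <- sample(names(p), background_len, replace = TRUE, prob = p)
    # choose non-overlapping slots by partitioning the background
    k <- length(lens)
    gap_total <- background_len - need
    cuts <- sort(sample.int(gap_total, k))
    gaps <- diff(c(0L, cuts))
    truth_rows <- vector("list", k)
    pos <- 0L; bg_used <- 0L
    out <- character(0)
    for (i in seq_len(k)) {
      g <- gaps[i]
      out <- c(out, paste(bg[(bg_used + 1L):(bg_used + g)], collapse = ""))
      bg_used <- bg_used + g
      pos <- pos + g
      idx <- copies[i]
      seq_i <- inserts[idx]
      strand <- if ("strand" %in% names(precursors) &&
                    idx <= nrow(precursors) &&
                    !is.na(precursors$strand[idx])) {
        precursors$strand[idx]
      } else {
        sample(c("sense", "antisense"), 1L)
      }
      planted <- if (strand == "antisense") as_dna(revcomp(seq_i)) else seq_i
      out <- c(out, planted)
      truth_rows[[i]] <- tibble::tibble(
        insert_index = idx, contig_id = contig_id,
        start = pos + 1L, end = pos + nchar(seq_i), strand = strand)
      pos <- pos + nchar(seq_i)
    }
    out <- c(out, paste(bg[(bg_used + 1L):background_len], collapse = ""))
    contig <- paste(out, collapse = "")
    placed <- dplyr::bind_rows(truth_rows)
    n_pre <- nrow(precursors)
    truth <- placed |>
      dplyr::filter(.data$insert_index <= n_pre) |>
      dplyr::mutate(family = precursors$family[.data$insert_index],
                    arm = precursors$arm[.data$insert_index],
                    defect = precursors$defect[.data$insert_index],
                    mature = precursors$mature[.data$insert_index],
                    star = precursors$star[.data$insert_index],
                    precursor = precursors$precursor[.data$insert_index]) |>
      dplyr::select(-"insert_index")
    te_loci <- placed |>
      dplyr::filter(.data$insert_index > n_pre)
    if (nrow(te_loci) > 0L) {
      te_loci <- dplyr::mutate(te_loci,
        id = te_inserts$id[.data$insert_index - n_pre],
        residues = te_inserts$residues[.data$insert_index - n_pre]) |>
        dplyr::select(-"insert_index")
    }
    list(contigs = tibble::tibble(id = contig_id, description = "synthetic",
                                  residues = contig),
         truth = truth, te_loci = te_loci)
  })
}

#' Generate small-RNA reads supporting planted duplexes
#'
#' Emits `per_mature` exact-embedding reads per distinct mature and
#' `per_star` per distinct star (the sequence itself, optionally with a
#' couple of random 3' bases), plus random noise reads of 18-26 nt.
#'
#' @param truth Tibble with `mature` and `star` columns.
#' @param per_mature,per_star Read depth per sequence (defaults 3).
#' @param noise_reads Number of random reads (default 100).
#' @param seed Integer seed.
#' @return A read tibble (`id`, `description`, `residues`).
#' @export
make_reads <- function(truth, per_mature = 3L, per_star = 3L,
                       noise_reads = 100L, seed = 1L) {
  with_seed(seed, {
    matures <- unique(truth$mature)
    stars <- unique(truth$star)
    emb <- function(s) paste0(s, rand_seq(sample(0:2, 1L)))
    reads <- c(
      unlist(lapply(matures, function(m) replicate(per_mature, emb(m)))),
      unlist(lapply(stars, function(s) replicate(per_star, emb(s)))),
      replicate(noise_reads, rand_seq(sample(18:26, 1L)))
    )
    tibble::tibble(id = sprintf("read%05d", seq_along(reads)),
                   description = "", residues = reads)
  })
}

#' Ready-made synthetic data sets
#'
#' * `basic` - 50 defect-free precursors (25 families, two members each,
#'   mixed arms, 1-2 designed duplex mismatches) planted in a 100 kb
#'   genome; references are the planted matures under miRBase-style ids.
#' * `te-heavy` - 12 precursors plus a repeat library; four precursors are
#'   TE-derived (a repeat overlaps most of the precursor).
#' * `srna` - 10 precursors in a 20 kb genome plus supporting reads
#'   (5x mature, 5x star, 200 noise reads).
#'
#' @param preset One of `"basic"`, `"te-heavy"`, `"srna"`.
#' @param seed Integer seed (default 1).
#' @return A list with `contigs`, `refs`, `truth`, and per preset
#'   `repeat_db`/`te_loci` or `reads`.
#' @export
fixture_preset <- function(preset = c("basic", "te-heavy", "srna"),
                           seed = 1L) {
  preset <- match.arg(preset)
  families <- c(156, 157, 159, 160, 164, 166, 167, 169, 171, 172, 319, 393,
                394, 395, 396, 397, 398, 399, 408, 482, 528, 529, 530, 818,
                845)
  build_set <- function(n, seed0) {
    fams <- rep(paste0("miR", families), length.out = n)
    letters_v <- rep(c("a", "b"), length.out = n)
    arms <- rep(c("5p", "3p"), length.out = n)
    pres <- purrr::map(seq_len(n), function(i) {
      mm <- if (i %% 2L == 0L) c(8L, 13L) else 10L
      make_precursor(fams[i], arm = arms[i],
                     duplex_mismatch_positions = mm,
                     seed = seed0 + i)
    }) |> dplyr::bind_rows()
    refs <- tibble::tibble(
      id = paste0("syn-", fams, letters_v, "-", arms),
      description = "planted reference",
      residues = pres$mature)
    list(precursors = pres, refs = refs)
  }
  if (preset == "basic") {
    s <- with_seed(seed, sample.int(10000L, 1L))
    bs <- build_set(50L, s)
    g <- make_genome(bs$precursors, background_len = 100000L, gc = 0.44,
                     seed = s + 50000L)
    c(g, list(refs = bs$refs))
  } else if (preset == "te-heavy") {
    s <- with_seed(seed, sample.int(10000L, 1L)) + 20000L
    bs <- build_set(12L, s)
    # four TE-derived precursors: the repeat is the precursor with a few
    # substitutions, so coverage is high and near-perfect matches exist
    tes <- with_seed(s + 999L, {
      derived <- purrr::map_chr(bs$precursors$precursor[1:4], function(p) {
        pos <- sample(nchar(p), 2L)
        for (q in pos) {
          substr(p, q, q) <- sample(setdiff(c("A", "C", "G", "U"),
                                            substr(p, q, q)), 1L)
        }
        p
      })
      tibble::tibble(
        id = c(paste0("TE", 1:4, "#DTC_Mariner"),
               paste0("TE", 5:6, "#RLC_Copia")),
        description = "synthetic repeat",
        residues = c(derived, rand_seq(400L), rand_seq(350L)))
    })
    g <- make_genome(bs$precursors, background_len = 60000L,
                     te_inserts = tes, seed = s + 50000L)
    c(g, list(refs = bs$refs, repeat_db = tes))
  } else {
    s <- with_seed(seed, sample.int(10000L, 1L)) + 40000L
    bs <- build_set(10L, s)
    g <- make_genome(bs$precursors, background_len = 20000L,
                     seed = s + 50000L)
    reads <- make_reads(g$truth, per_mature = 5L, per_star = 5L,
                        noise_reads = 200L, seed = s + 60000L)
    c(g, list(refs = bs$refs, reads = reads))
  }
}
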