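# Independent oracles: deliberately naive implementations, kept free of the
# package's kernels so they can audit them.

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# position-by-position brute-force scanner (single strand)
oracle_scan_strand <- function(text, pattern, k) {
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pc); n <- length(tc)
  if (m > n) return(tibble::tibble(start = integer(), mismatches = integer()))
  res <- lapply(seq_len(n - m + 1L), function(s) {
    mm <- sum(tc[s:(s + m - 1L)] != pc)
    if (mm <= k) c(s, mm) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(tibble::tibble(start = integer(), mismatches = integer()))
  tibble::tibble(start = res[, 1], mismatches = res[, 2])
}

# both strands, in the hit tibble shape of scan_mirna_hits()
oracle_scan <- function(contig, ref, k, contig_id = "c", ref_id = "r") {
  L <- nchar(contig)
  m <- nchar(ref)
  s <- oracle_scan_strand(contig, ref, k)
  a <- oracle_scan_strand(revcomp(contig), ref, k)
  out <- dplyr::bind_rows(
    tibble::tibble(contig_id = contig_id, start = s$start,
                   end = s$start + m - 1L,
                   strand = rep("sense", nrow(s)),
                   ref_id = ref_id, mismatches = s$mismatches),
    tibble::tibble(contig_id = contig_id,
                   start = L - (a$start + m - 1L) + 1L,
                   end = L - a$start + 1L,
                   strand = rep("antisense", nrow(a)),
                   ref_id = ref_id, mismatches = a$mismatches)
  )
  out[order(out$start, out$strand), ]
}

# exhaustive enumeration of all pseudoknot-free structures compatible with
# the sequence (canonical + wobble pairs, hairpin loops >= 3); returns the
# minimum energy under the package's structure-energy evaluator
can_pair_oracle <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

enumerate_structures <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity) # i unpaired
    ks <- if (i + 4L <= j) (i + 4L):j else integer(0)
    for (k in ks) {
      if (!can_pair_oracle(ch[i], ch[k])) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (s1 in inner) for (s2 in outer) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

oracle_min_energy <- function(residues) {
  n <- nchar(residues)
  structs <- enumerate_structures(residues)
  best <- 0 # open chain
  for (s in structs) {
    if (length(s) == 0L) next
    p <- integer(n)
    for (pr in s) { p[pr[1]] <- pr[2]; p[pr[2]] <- pr[1] }
    e <- structure_energy(residues, p)
    if (e < best) best <- e
  }
  best
}

# brute-force covered positions for interval sets
oracle_covered <- function(starts, ends) {
  length(unique(unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))))
}
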