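mk_seqs <- function(...) {
  x <- c(...)
  tibble::tibble(id = names(x), description = "", residues = unname(x))
}

test_that("an exact reverse-complement is one antisense hit", {
  ref <- "AAGGCUAGCUGAUCGGAUCC" # not self-reverse-complementary
  contig <- paste0("GGGGG", as_dna(revcomp(ref)), "GGGGG")
  hits <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "antisense")
  expect_equal(hits$mismatches, 0L)
  expect_equal(c(hits$start, hits$end), c(6L, 25L))
  expect_equal(hits$mature, ref)
})

test_that("hits beyond the mismatch ceiling are excluded", {
  ref <- strrep("ACGU", 5)
  mut <- ref
  substr(mut, 1, 1) <- "U"; substr(mut, 9, 9) <- "C"; substr(mut, 17, 17) <- "G"
  hits <- scan_mirna_hits(mk_seqs(c = mut), mk_seqs(r = ref), 2L)
  expect_equal(nrow(hits[hits$strand == "sense", ]), 0L)
})

test_that("scan equals the brute-force comparator on random instances", {
  set.seed(101)
  for (i in 1:60) {
    contig <- rand_rna(sample(60:500, 1))
    ref <- rand_rna(sample(20:24, 1))
    # plant a mutated copy half the time so hits actually occur
    if (i %% 2 == 0) {
      s <- sample(nchar(contig) - nchar(ref), 1)
      planted <- ref
      for (q in sample(nchar(ref), sample(0:3, 1)))
        substr(planted, q, q) <- sample(c("A", "C", "G", "U"), 1)
      substr(contig, s, s + nchar(ref) - 1) <- planted
    }
    k <- sample(0:3, 1)
    got <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), k)
    want <- oracle_scan(contig, ref, k)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got[, c("start", "end", "strand", "mismatches")],
                   want[, c("start", "end", "strand", "mismatches")])
      # reported mismatch positions are consistent with the count
      expect_equal(lengths(got$mismatch_positions), got$mismatches)
    }
  }
})

test_that("scan is strand-symmetric and monotone in the mismatch ceiling", {
  set.seed(202)
  for (i in 1:20) {
    contig <- rand_rna(300)
    s <- sample(250, 1)
    ref <- substr(contig, s, s + 20)
    substr(contig, s + 3, s + 3) <- "A" # near-copy stays in range
    hits_f <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), 2L)
    hits_r <- scan_mirna_hits(mk_seqs(c = as_dna(revcomp(contig))),
                              mk_seqs(r = ref), 2L)
    L <- nchar(contig)
    mapped <- hits_r
    mapped$start2 <- L - hits_r$end + 1L
    mapped$end2 <- L - hits_r$start + 1L
    mapped$strand2 <- ifelse(hits_r$strand == "sense", "antisense", "sense")
    mapped <- mapped[order(mapped$start2, mapped$strand2), ]
    expect_equal(hits_f$start,  mapped$start2)
    expect_equal(hits_f$end,    mapped$end2)
    expect_equal(hits_f$strand, mapped$strand2)
    # monotonicity: hit set grows with k
    for (k in 0:2) {
      a <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), k)
      b <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), k + 1L)
      key <- function(h) paste(h$start, h$strand)
      expect_true(all(key(a) %in% key(b)))
    }
  }
})

test_that("scan with k = 0 equals naive exact substring search", {
  set.seed(303)
  contig <- paste(replicate(20, "ACGU"), collapse = "")
  ref <- strrep("ACGU", 5)
  hits <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), 0L)
  sense <- hits[hits$strand == "sense", ]
  naive <- which(vapply(1:(nchar(contig) - 19), function(s)
    substr(contig, s, s + 19) == ref, logical(1)))
  expect_equal(sense$start, naive)
})

test_that("scan agrees with Biostrings matchPattern as a cross-check", {
  skip_if_not_installed("Biostrings")
  set.seed(404)
  for (i in 1:10) {
    contig <- rand_rna(400)
    ref <- rand_rna(21)
    s <- sample(300, 1)
    substr(contig, s, s + 20) <- ref
    k <- sample(0:2, 1)
    got <- scan_mirna_hits(mk_seqs(c = contig), mk_seqs(r = ref), k)
    sense <- got[got$strand == "sense", ]
    bm <- Biostrings::matchPattern(Biostrings::RNAString(ref),
                                   Biostrings::RNAString(contig),
                                   max.mismatch = k, with.indels = FALSE)
    expect_equal(sense$start, Biostrings::start(bm))
  }
})

test_that("references with N are skipped with a warning", {
  refs <- mk_seqs(good = strrep("AC", 10), bad = paste0(strrep("AC", 9), "NN"))
  expect_warning(
    hits <- scan_mirna_hits(mk_seqs(c = strrep("AC", 30)), refs, 0L),
    "bad")
  expect_true(all(hits$ref_id == "good"))
})

test_that("read matching places the reference and honours thresholds", {
  ref <- rand_rna(21)
  reads <- mk_seqs(r1 = paste0("AC", ref, "G"), r2 = rand_rna(24))
  refs <- mk_seqs(miR = ref)
  m <- match_reads_to_refs(reads, refs, max_mismatch = 0L)
  expect_equal(m$read_id, "r1")
  expect_equal(c(m$read_start, m$read_end), c(3L, 23L))
  expect_equal(m$mismatches, 0L)

  # a 24-nt read holding the ref with one substitution
  mut <- ref; substr(mut, 10, 10) <- setdiff(c("A","C","G","U"),
                                             substr(ref, 10, 10))[1]
  m2 <- match_reads_to_refs(mk_seqs(r = paste0("A", mut, "GG")), refs, 3L)
  expect_equal(m2$mismatches, 1L)
  expect_equal(m2$read_end - m2$read_start + 1L, 21L)

  # short read placed inside the reference, full read must align
  m3 <- match_reads_to_refs(mk_seqs(r = substr(ref, 3, 20)), refs, 0L)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$read_start, m3$read_end), c(1L, 18L))

  # beyond threshold: no row
  far <- ref
  for (q in c(2, 7, 12, 18)) substr(far, q, q) <-
      setdiff(c("A","C","G","U"), substr(ref, q, q))[1]
  expect_equal(nrow(match_reads_to_refs(mk_seqs(r = far), refs, 3L)), 0L)
})

test_that("trimmed reads rescan to zero-mismatch hits (sRNA mode)", {
  set.seed(9)
  genome_core <- rand_rna(200)
  ref <- substr(genome_core, 50, 70)
  read <- paste0("GG", ref, "AAC") # adapter-trimmed read holding the ref
  matches <- match_reads_to_refs(mk_seqs(rd = read), mk_seqs(miR = ref), 2L)
  trimmed <- trim_to_match(matches, mk_seqs(rd = read))
  expect_equal(trimmed$residues, ref)
  expect_equal(trimmed$id, "rd|miR")
  hits <- scan_mirna_hits(mk_seqs(g = genome_core), trimmed, 0L)
  expect_true(any(hits$start == 50 & hits$strand == "sense"))
})
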