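test_that("windows clip at contig edges per the coordinate rules", {
  # hit centred in a 700 nt contig: window is the whole contig
  hit <- list(start = 341L, end = 361L, strand = "sense")
  w <- build_window(hit, rand_rna(700), 700L)
  expect_equal(c(w$window_start, w$window_end), c(1L, 700L))
  expect_equal(c(w$mature_start, w$mature_end), c(341L, 361L))

  # hit at the very start of a long contig: clipped left
  set.seed(1)
  contig <- rand_rna(10000)
  w2 <- build_window(list(start = 1L, end = 21L, strand = "sense"),
                     contig, 700L)
  expect_equal(c(w2$window_start, w2$window_end), c(1L, 371L))
  expect_equal(c(w2$mature_start, w2$mature_end), c(1L, 21L))

  # antisense: window residues are the reverse complement of the slice
  w3 <- build_window(list(start = 501L, end = 521L, strand = "antisense"),
                     contig, 700L)
  slice <- substr(contig, w3$window_start, w3$window_end)
  expect_equal(w3$residues, revcomp(slice))
  expect_equal(substr(w3$residues, w3$mature_start, w3$mature_end),
               revcomp(substr(contig, 501, 521)))
  expect_error(build_window(hit, rand_rna(700), 80L), "4x")
})

test_that("planted duplex mismatches are counted and suspects flagged", {
  # perfect duplex -> suspect
  p0 <- make_precursor("miR999", seed = 5)
  f0 <- fold_rna(p0$precursor)
  a0 <- sumir:::assess_duplex(f0, p0$mature_start, p0$mature_end)
  expect_equal(a0$duplex_mismatches, 0L)
  expect_true(a0$suspect)

  # two internal bulged mature positions -> 2 mismatches, not suspect
  p2 <- make_precursor("miR999", duplex_mismatch_positions = c(8L, 13L),
                       seed = 5)
  f2 <- fold_rna(p2$precursor)
  a2 <- sumir:::assess_duplex(f2, p2$mature_start, p2$mature_end)
  expect_equal(a2$duplex_mismatches, 2L)
  expect_false(a2$suspect)

  # unstructured poly-A window -> rejection
  aA <- sumir:::assess_duplex(fold_rna(strrep("A", 80)), 10, 30)
  expect_equal(aA$status, "rejected")
})

test_that("excision spans 20 nt beyond both duplex ends and clips", {
  # duplex at window [21,41] mature / [86,106] star -> precursor [1,126]
  lo <- min(21, 86) - 20; hi <- max(41, 106) + 20
  expect_equal(c(max(1, lo), hi), c(1, 126))
  # in vivo: construct a window holding a planted hairpin with flanks
  set.seed(33)
  p <- make_precursor("miR1", duplex_mismatch_positions = 10L, seed = 33)
  win <- paste0(rand_rna(40), p$precursor, rand_rna(40))
  f <- fold_rna(win)
  a <- sumir:::assess_duplex(f, 40 + p$mature_start, 40 + p$mature_end)
  expect_equal(a$status, "ok")
  ex <- excise_precursor(win, a)
  expect_equal(ex$status, "ok")
  lo_exp <- min(a$mature_start, a$star_start) - 20L
  hi_exp <- max(a$mature_end, a$star_end) + 20L
  expect_equal(ex$precursor, substr(win, lo_exp, hi_exp))
  # refold keeps the duplex: mature still mostly paired into the star
  expect_lte(ex$duplex_mismatches, 3L)
})

test_that("energy statistics follow the MFEI definitions", {
  s <- precursor_stats(-60, paste0(strrep("GC", 30), strrep("AU", 30)))
  expect_equal(s$amfe, -50)
  expect_equal(s$gc_fraction, 0.5)
  expect_equal(s$mfei, 1.0) # |AMFE| / GC%
  # zero-GC precursor: MFEI undefined
  s2 <- precursor_stats(-10, strrep("AU", 50))
  expect_true(is.na(s2$mfei))
  # batch recomputation oracle
  set.seed(44)
  for (i in 1:20) {
    seq <- rand_rna(sample(80:160, 1))
    mfe <- -runif(1, 20, 80)
    st <- precursor_stats(mfe, seq)
    gc <- lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
    expect_equal(st$amfe, mfe / nchar(seq) * 100)
    expect_equal(st$gc_fraction, gc)
    expect_equal(st$mfei, abs(st$amfe) / (gc * 100))
  }
})

test_that("accepted candidates contain their duplex and near-equal arms", {
  fx <- fixture_preset("srna", seed = 2)
  hits <- scan_mirna_hits(fx$contigs, fx$refs, 2L)
  cand <- fold_hairpins(hits, fx$contigs)
  ok <- cand[cand$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$mature_start >= 1))
  expect_true(all(ok$mature_end <= nchar(ok$precursor)))
  expect_true(all(ok$star_start >= 1))
  expect_true(all(ok$star_end <= nchar(ok$precursor)))
  # mature and star lengths differ by at most 2 nt
  expect_true(all(abs((ok$mature_end - ok$mature_start) -
                      (ok$star_end - ok$star_start)) <= 2))
  # suspect flag is exactly the zero-mismatch condition
  expect_equal(ok$suspect, ok$duplex_mismatches == 0L)
  # precursor coordinates map back onto the contig
  for (k in seq_len(nrow(ok))) {
    seg <- substr(fx$contigs$residues[fx$contigs$id == ok$contig_id[k]],
                  ok$precursor_contig_start[k], ok$precursor_contig_end[k])
    seg <- if (ok$strand[k] == "antisense") revcomp(seg) else as_rna(seg)
    expect_equal(seg, ok$precursor[k])
  }
})
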