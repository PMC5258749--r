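mk_pred <- function(mature, precursor, star = NULL) {
  tibble::tibble(assigned_name = "miRx-5p", family = "miRx",
                 mature = mature, precursor = precursor,
                 star_list = if (is.null(star)) revcomp(mature) else star,
                 mature_start = 1L, mature_end = nchar(mature),
                 star_start = nchar(precursor) - nchar(mature) + 1L,
                 star_end = nchar(precursor))
}

test_that("contaminant screen flags only above both 95% thresholds", {
  set.seed(90)
  mature <- rand_rna(21)
  pre <- paste0(mature, rand_rna(79))
  pred <- mk_pred(mature, pre)

  # mature identical to a tRNA fragment: flagged
  db <- tibble::tibble(id = "tRNA1", description = "",
                       residues = paste0(rand_rna(15), mature, rand_rna(15)))
  expect_true(screen_contaminants(pred, db))

  # best hit at 94% identity over the full precursor: not flagged
  mut <- pre
  for (q in seq(5, 100, by = 16)) # 6 substitutions in 100 nt = 94%
    substr(mut, q, q) <- setdiff(c("A","C","G","U"), substr(mut, q, q))[1]
  mut_mature <- substr(mut, 1, 21)
  pred2 <- mk_pred(mut_mature, mut)
  db2 <- tibble::tibble(id = "x", description = "", residues = pre)
  # identity of precursor vs db is 94/100; mature contains 2 of the
  # substitutions so it is below 95% as well
  expect_false(screen_contaminants(pred2, db2))

  # empty database: screen skipped
  expect_false(any(screen_contaminants(pred, NULL)))

  # planted decoys among clean predictions: exactly the decoys flag
  trna <- rand_rna(75)
  preds <- dplyr::bind_rows(
    purrr::map(1:8, ~mk_pred(rand_rna(21), rand_rna(90))),
    mk_pred(substr(trna, 10, 30), substr(trna, 5, 70))
  )
  flags <- screen_contaminants(preds,
                               tibble::tibble(id = "t", description = "",
                                              residues = trna))
  expect_equal(flags, c(rep(FALSE, 8), TRUE))
})

test_that("the identity boundary is strict at 95%", {
  # 19/20 matches = 95% exactly -> NOT flagged; 20/20 -> flagged
  q <- strrep("AC", 10)
  subj_exact <- paste0("GGG", q, "GGG")
  q_one_off <- q
  substr(q_one_off, 10, 10) <- "U"
  pred_exact <- mk_pred(strrep("AC", 12), paste0(q, rand_rna(2)))
  b <- sumir:::best_ungapped(q_one_off, subj_exact, cov_min = 0.95)
  expect_equal(b$identity, 0.95)
  expect_false(b$identity > 0.95) # boundary: 95.0% does not exceed
  b2 <- sumir:::best_ungapped(q, subj_exact, cov_min = 0.95)
  expect_true(b2$identity > 0.95)
})

test_that("precursor expression requires containment above thresholds", {
  set.seed(91)
  pre <- rand_rna(100)
  transcripts <- tibble::tibble(
    id = c("t1", "t2"), description = "",
    residues = c(paste0(rand_rna(50), pre, rand_rna(50)),
                 paste0(substr(pre, 1, 50), rand_rna(200))))
  expect_equal(precursor_expression(c(pre, rand_rna(100)), transcripts),
               c(TRUE, FALSE))
  # a 50%-length match is not expression
  expect_false(precursor_expression(pre, transcripts[2, ]))
  # transcriptome mode self-consistency: precursors against their own
  # source transcripts are all expressed
  expect_true(all(precursor_expression(
    substr(transcripts$residues, 10, 80), transcripts)))
})

test_that("duplex expression needs three exact reads on both sides", {
  set.seed(92)
  mature <- rand_rna(21)
  star <- rand_rna(21)
  pred <- mk_pred(mature, paste0(mature, rand_rna(40), star), star)
  reads_for <- function(n_m, n_s, mutate_mature = FALSE) {
    m <- if (mutate_mature) {
      x <- mature; substr(x, 5, 5) <- setdiff(c("A","C","G","U"),
                                              substr(x, 5, 5))[1]; x
    } else mature
    tibble::tibble(
      id = sprintf("r%d", seq_len(n_m + n_s + 5)), description = "",
      residues = c(rep(paste0(m, "AG"), n_m), rep(star, n_s),
                   replicate(5, rand_rna(24))))
  }
  e33 <- mature_expression(pred, reads_for(3, 3))
  expect_equal(c(e33$mature_reads, e33$star_reads), c(3L, 3L))
  expect_true(e33$duplex_expressed)
  e32 <- mature_expression(pred, reads_for(3, 2))
  expect_false(e32$duplex_expressed)
  # 1-mismatch reads count zero: exactness is total
  em <- mature_expression(pred, reads_for(3, 3, mutate_mature = TRUE))
  expect_equal(em$mature_reads, 0L)
  # read-count totals are invariant to read file ordering
  rds <- reads_for(4, 5)
  e_fwd <- mature_expression(pred, rds)
  e_rev <- mature_expression(pred, rds[rev(seq_len(nrow(rds))), ])
  expect_equal(e_fwd, e_rev)
})

test_that("TE coverage and the siRNA rule sit exactly on their boundaries", {
  set.seed(93)
  pre <- rand_rna(100)
  rep_at <- function(lo, hi) tibble::tibble(
    id = "TE1#DTC_Mariner", description = "",
    residues = substr(pre, lo, hi))
  # merged coverage 50/100: not a TE-miR (strictly more than 50%)
  te50 <- classify_te(pre, rep_at(1, 50), min_span = 20L)
  expect_equal(te50$te_coverage_fraction, 0.5)
  expect_false(te50$te_mir)
  # 51/100: TE-miR
  te51 <- classify_te(pre, rep_at(1, 51), min_span = 20L)
  expect_true(te51$te_mir)
  expect_equal(te51$te_family, "DTC_Mariner")

  # siRNA candidate: full-length alignment with <= 3 mismatches
  mut_n <- function(n) {
    x <- pre
    for (q in seq(10, 10 + 7 * (n - 1), by = 7))
      substr(x, q, q) <- setdiff(c("A","C","G","U"), substr(x, q, q))[1]
    tibble::tibble(id = "TEs#RLC", description = "", residues = x)
  }
  s3 <- classify_te(pre, mut_n(3))
  expect_true(s3$sirna_candidate)
  s4 <- classify_te(pre, mut_n(4))
  expect_false(s4$sirna_candidate)
  # sirna implies TE-miR (a >= 90% span is > 50% coverage)
  expect_true(!s3$sirna_candidate || s3$te_mir)
  # no repeats: all false
  e <- classify_te(pre, NULL)
  expect_false(e$te_mir || e$sirna_candidate)
})

test_that("the evidence table assembles all screens per miRNA", {
  fx <- fixture_preset("te-heavy", seed = 8)
  run <- run_pipeline(fx$contigs, fx$refs, sumir_config(),
                      repeat_db = fx$repeat_db)
  ev <- run$evidence
  expect_equal(nrow(ev), nrow(run$predicted))
  expect_true(all(ev$te_coverage_fraction >= 0 & ev$te_coverage_fraction <= 1))
  expect_true(all(ev$sirna_candidate <= ev$te_mir)) # implication
  # the four TE-derived precursor families are classified TE-miR
  te_fams <- fx$truth$family[1:4]
  flagged <- run$predicted$family[ev$te_mir]
  expect_true(any(te_fams %in% flagged))
})
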