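judge_one <- function(p) {
  hit <- tibble::tibble(
    contig_id = "c", start = 1L, end = nchar(p$mature), strand = "sense",
    ref_id = "syn-miR1a-5p", mismatches = 0L,
    mismatch_positions = list(integer(0)), mature = p$mature)
  contig <- tibble::tibble(id = "c", description = "",
                           residues = paste0(rand_rna(30), p$precursor,
                                             rand_rna(30)))
  hits <- scan_mirna_hits(contig, tibble::tibble(id = "syn-miR1a-5p",
                                                 description = "",
                                                 residues = p$mature), 0L)
  cand <- fold_hairpins(hits, contig)
  judge_candidates(cand)
}

test_that("the verdict suite separates the hairpin classes exactly", {
  set.seed(50)
  clean <- make_precursor("miR1", duplex_mismatch_positions = 10L, seed = 61)
  head_p <- make_precursor("miR1", duplex_mismatch_positions = 8L,
                           defect = "head", seed = 62)
  dicer <- make_precursor("miR1", duplex_mismatch_positions = 10L,
                          defect = "dicer-cut", seed = 63)
  multi <- make_precursor("miR1", duplex_mismatch_positions = 10L,
                          defect = "multiloop", seed = 64)
  perfect <- make_precursor("miR1", seed = 65)

  # a perfect hairpin also carries the mature on its star arm (the scan
  # legitimately reports the antisense placement); judge the sense-arm row
  v <- function(p) {
    j <- judge_one(p)
    j <- j[j$status == "ok" & j$strand == "sense", ]
    expect_equal(nrow(j), 1L)
    j
  }
  expect_equal(v(clean)$verdict, "OK")
  expect_equal(v(head_p)$verdict, "Head")
  expect_equal(v(dicer)$verdict, "Dicer-cut")
  expect_equal(v(multi)$verdict, "Multiloop")
  pj <- v(perfect)
  expect_true(pj$suspect)
  expect_equal(pj$duplex_mismatches, 0L)
})

test_that("every candidate receives exactly one verdict", {
  fx <- fixture_preset("srna", seed = 3)
  hits <- scan_mirna_hits(fx$contigs, fx$refs, 2L)
  j <- judge_candidates(fold_hairpins(hits, fx$contigs))
  ok_rows <- j[j$status == "ok", ]
  expect_true(all(!is.na(ok_rows$verdict)))
  expect_true(all(ok_rows$verdict %in%
                    c("OK", "Multiloop", "Head", "Dicer-cut", "N-in-mature")))
  expect_equal(sum(table(ok_rows$verdict)), nrow(ok_rows))
})

test_that("N in the mature is rejected at judging", {
  # craft a judged row directly: an OK candidate whose mature holds an N
  fx <- fixture_preset("srna", seed = 4)
  hits <- scan_mirna_hits(fx$contigs, fx$refs, 2L)
  cand <- fold_hairpins(hits, fx$contigs)
  cand$mature[cand$status == "ok"][1] <-
    sub("^.", "N", cand$mature[cand$status == "ok"][1])
  j <- judge_candidates(cand)
  expect_equal(j$verdict[j$status == "ok"][1], "N-in-mature")
})

test_that("naming rules 1-3 hold over the whole id grammar", {
  # the three canonical examples
  expect_equal(assign_mirna_name("miR156a-3p", "3p"), "miR156-3p")
  expect_equal(assign_mirna_name("miR156a", "3p"), "miR156-3p")
  expect_equal(assign_mirna_name("miR156a-3p", "5p"), "miR156")
  # full grammar: species prefix x letter x suffix x detected arm
  for (sp in c("", "aly-", "tae-")) {
    for (letter in c("", "a", "g")) {
      for (suffix in c("", "-5p", "-3p")) {
        for (arm in c("5p", "3p")) {
          id <- paste0(sp, "miR156", letter, suffix)
          got <- assign_mirna_name(id, arm)
          want <- if (suffix == "") paste0("miR156-", arm)
                  else if (suffix == paste0("-", arm)) paste0("miR156-", arm)
                  else "miR156"
          expect_equal(got, want, info = paste(id, arm))
        }
      }
    }
  }
  expect_error(assign_mirna_name("not-a-mirna", "5p"), "unparseable")
})

test_that("redundant annotations resolve to the closest homolog", {
  set.seed(70)
  p <- make_precursor("miR156", duplex_mismatch_positions = 10L, seed = 71)
  contig <- tibble::tibble(id = "c", description = "",
                           residues = paste0(rand_rna(30), p$precursor,
                                             rand_rna(30)))
  # ref156 matches the planted mature with 1 mismatch, ref157 with 2
  mut <- function(s, at) {
    for (q in at) substr(s, q, q) <- setdiff(c("A","C","G","U"),
                                             substr(s, q, q))[1]
    s
  }
  refs <- tibble::tibble(
    id = c("aly-miR156g-5p", "aly-miR157d-5p"),
    description = "",
    residues = c(mut(p$mature, 4L), mut(p$mature, c(4L, 17L))))
  hits <- scan_mirna_hits(contig, refs, 2L)
  j <- judge_candidates(fold_hairpins(hits, contig))
  pred <- predict_mirnas(j)
  pred <- pred[pred$mature == p$mature, ] # drop the star-arm placement
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$homolog_ids, "aly-miR156g-5p")
  expect_equal(pred$family, "miR156")

  # equal similarity: both ids kept, comma-joined
  refs2 <- tibble::tibble(
    id = c("aly-miR156g-5p", "aly-miR157d-5p"),
    description = "",
    residues = c(mut(p$mature, 4L), mut(p$mature, 17L)))
  hits2 <- scan_mirna_hits(contig, refs2, 2L)
  on_mature <- function(pred) pred[pred$mature == p$mature, ]
  pred2 <- on_mature(predict_mirnas(judge_candidates(
    fold_hairpins(hits2, contig))))
  expect_equal(pred2$homolog_ids, "aly-miR156g-5p,aly-miR157d-5p")

  # precursor-level tie-break: the family with the matching precursor wins
  ref_pre <- tibble::tibble(id = "osa-miR157d",
                            description = "",
                            residues = p$precursor)
  pred3 <- on_mature(predict_mirnas(judge_candidates(
    fold_hairpins(hits2, contig)), ref_precursors = ref_pre))
  expect_equal(pred3$homolog_ids, "aly-miR157d-5p")
  expect_equal(pred3$family, "miR157")

  # no reference precursors supplied: the doublet stays
  pred4 <- on_mature(predict_mirnas(judge_candidates(
    fold_hairpins(hits2, contig)), ref_precursors = NULL))
  expect_equal(pred4$homolog_ids, "aly-miR156g-5p,aly-miR157d-5p")
})

test_that("predictions are unique by location and numbered in families", {
  fx <- fixture_preset("srna", seed = 5)
  run <- run_pipeline(fx$contigs, fx$refs, sumir_config())
  pred <- run$predicted
  key <- paste(pred$contig_id, pred$precursor_contig_start, pred$mature)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(anyDuplicated(pred$assigned_name), 0L)
})
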