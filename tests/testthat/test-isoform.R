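test_that("splice_candidate removes the intron and keeps the books", {
  g <- make_gene(seed = 2)
  tx <- extract_mrna(g$sequence, g$model)
  cand <- scan_cryptic_introns(g$sequence, g$model)[1, ]
  v <- splice_candidate(tx, cand)
  expect_equal(nchar(v$mrna) + cand$length, nchar(tx$mrna))  # conservation
  expect_equal(length(v$junctions), length(tx$junctions) + 1L)
  expect_identical(v$mrna, g$truth$variant_mrna)
  # the new junction sits at the fusion point
  fusion <- genomic_to_mrna(tx, cand$intron_start) - 1L
  expect_true(fusion %in% v$junctions)
})

test_that("splice_candidate rejects intervals spanning exon boundaries", {
  g <- make_gene(seed = 2)
  tx <- extract_mrna(g$sequence, g$model)
  ex <- g$model$exons
  expect_error(
    splice_candidate(tx, list(intron_start = ex$end[1] - 5L,
                              intron_end = ex$start[2] + 5L)),
    "not contained")
  # removing a full exon end is an exon skip, not a cryptic intron
  expect_error(
    splice_candidate(tx, list(intron_start = ex$start[2],
                              intron_end = ex$start[2] + 10L)),
    "exon end")
})

test_that("find_orf translates from the annotated start", {
  tx <- toy_transcript("ATGAAATAA")
  rec <- find_orf(tx)
  expect_equal(rec$orf_length_nt, 9L)
  expect_equal(rec$protein, "MK")
  expect_false(rec$run_through)
  expect_equal(rec$orf_start, 0L)
  expect_equal(rec$orf_stop, 9L)
})

test_that("find_orf flags run-through transcripts", {
  rec <- find_orf(toy_transcript("ATGAAAAAAAAA"))
  expect_true(rec$run_through)
  expect_equal(rec$protein, "MKKK")
  expect_true(is.na(rec$nmd_flag))
})

test_that("find_orf errors when the start is not ATG", {
  expect_error(find_orf(toy_transcript("TTGAAATAA")), "ATG")
  expect_error(find_orf(toy_transcript("CCCCCC")), "ATG")
  # first_atg policy scans for the 5'-most ATG
  rec <- find_orf(toy_transcript("CCATGAAATAACC"), start_policy = "first_atg")
  expect_equal(rec$protein, "MK")
})

test_that("find_orf agrees with the codon-walk oracle on random transcripts", {
  set.seed(41)
  for (rep in 1:50) {
    body <- rand_seq(3 * sample(10:60, 1))
    mrna <- paste0("ATG", body)
    rec <- find_orf(toy_transcript(mrna))
    orc <- oracle_orf(mrna, 1L)
    expect_equal(rec$protein, orc$protein)
    expect_equal(rec$orf_length_nt,
                 if (orc$stopped) orc$orf_nt else 3L * (nchar(mrna) %/% 3L))
  }
})

test_that("the 50-nt NMD rule uses the final junction", {
  fake <- function(junctions, orf_stop)
    structure(list(transcript = list(junctions = junctions),
                   orf_stop = orf_stop),
              class = "isoform_record")
  r <- nmd_check(fake(c(100L, 250L), 180L))
  expect_equal(r$ptc_distance, 70L)
  expect_true(r$nmd_flag)
  r <- nmd_check(fake(c(100L, 250L), 230L))
  expect_equal(r$ptc_distance, 20L)
  expect_false(r$nmd_flag)
  # stop downstream of the final junction: negative distance, never flagged
  r <- nmd_check(fake(c(100L, 250L), 300L))
  expect_equal(r$ptc_distance, -50L)
  expect_false(r$nmd_flag)
  # junction-less mRNA cannot trigger the rule
  r <- nmd_check(fake(integer(0), 10L))
  expect_false(r$nmd_flag)
})

test_that("NMD dichotomy: a stop in the final exon is never flagged", {
  set.seed(43)
  for (rep in 1:50) {
    junctions <- sort(sample(50:500, sample(1:4, 1)))
    stop_end <- max(junctions) + sample(0:100, 1)  # at/after final junction
    r <- nmd_check(structure(
      list(transcript = list(junctions = junctions), orf_stop = stop_end),
      class = "isoform_record"))
    expect_false(r$nmd_flag)
  }
})

test_that("variant frame integrity: protein equals piecewise translation", {
  g <- make_gene(seed = 17)
  tx <- extract_mrna(g$sequence, g$model)
  v <- splice_candidate(tx, scan_cryptic_introns(g$sequence, g$model)[1, ])
  rec <- find_orf(v)
  expect_identical(rec$protein, g$truth$variant_protein)
  expect_false(rec$nmd_flag)   # stop is in the last exon segment
  # independent translation of the CDS slice of the variant mRNA
  cds_start <- genomic_to_mrna(v, g$model$cds_start)
  orc <- oracle_orf(v$mrna, cds_start)
  expect_identical(rec$protein, orc$protein)
})
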