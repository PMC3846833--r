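test_that("single-lesion orthologs classify to their ground truth", {
  g <- make_gene(seed = 3)
  degr <- c(sheep = "none", cow = "none", dog = "lost_motif_donor",
            shrew = "lost_motif_acceptor", rat = "lost_motif_branch",
            horse = "premature_stop", megabat = "frameshift_indel")
  for (seed in 1:5) {
    os <- make_ortholog_set(g, degr,
                            evidence = c(sheep = "confirmed_transcript"),
                            seed = seed)
    calls <- classify_set(os$sequences, os$table)
    expect_equal(calls$call, os$truth$call, info = paste("seed", seed))
  }
})

test_that("evidence separates fixed from putative", {
  g <- make_gene(seed = 3)
  os <- make_ortholog_set(g, c(a = "none", b = "none"),
                          evidence = c(a = "confirmed_transcript", b = "none"),
                          seed = 1)
  calls <- classify_set(os$sequences, os$table)
  expect_equal(calls$call, c("fixed", "putative"))
})

test_that("motif flags drive the call table as specified", {
  g <- make_gene(seed = 3)
  os <- make_ortholog_set(g, c(x = "lost_motif_donor"), seed = 1)
  call <- classify_set(os$sequences, os$table)
  expect_false(call$donor_ok)
  expect_true(call$acceptor_ok)
  expect_equal(call$call, "lost_motif")

  os <- make_ortholog_set(g, c(x = "lost_motif_branch"), seed = 1)
  call <- classify_set(os$sequences, os$table)
  expect_false(call$branch_ok)
  expect_true(call$donor_ok && call$acceptor_ok)
  expect_equal(call$call, "lost_motif")

  os <- make_ortholog_set(g, c(x = "premature_stop"), seed = 1)
  call <- classify_set(os$sequences, os$table)
  expect_equal(call$orf_status, "premature_stop")
  expect_equal(call$call, "lost_orf")

  os <- make_ortholog_set(g, c(x = "frameshift_indel"), seed = 1)
  call <- classify_set(os$sequences, os$table)
  expect_equal(call$orf_status, "frameshift_indel")
  expect_equal(call$call, "lost_orf")
})

test_that("degrading exactly one motif flips a fixed call to lost_motif", {
  g <- make_gene(seed = 19)
  for (lesion in c("lost_motif_donor", "lost_motif_acceptor",
                   "lost_motif_branch")) {
    os <- make_ortholog_set(g, setNames(c("none", lesion), c("ref", "mut")),
                            evidence = c(ref = "confirmed_transcript"),
                            seed = 7)
    calls <- classify_set(os$sequences, os$table)
    expect_equal(calls$call[calls$species == "ref"], "fixed")
    expect_equal(calls$call[calls$species == "mut"], "lost_motif")
  }
})

test_that("the call function is total and deterministic over the flag space", {
  # drive every donor x acceptor x branch x orf combination through
  # classify_species with purpose-built sequences
  base_intron <- function(donor = "GT", acceptor = "AG") {
    paste0(donor, strrep("A", 20), "TACTAAC", strrep("A", 3),
           strrep("T", 15), acceptor)
  }
  for (donor_ok in c(TRUE, FALSE)) for (acc_ok in c(TRUE, FALSE))
    for (branch_ok in c(TRUE, FALSE)) {
      intron <- base_intron(if (donor_ok) "GT" else "GC",
                            if (acc_ok) "AG" else "AC")
      if (!branch_ok) intron <- sub("TACTAAC", "GGGGGGG", intron)
      # exon: 6 nt coding, intron, then coding with terminal stop
      s <- paste0("ATGAAA", intron, "AAATTTTAA")
      call <- classify_species(s, c(7L, 6L + nchar(intron)), "t",
                               reference_orf_codons = 5L)
      expect_equal(call$donor_ok, donor_ok)
      expect_equal(call$acceptor_ok, acc_ok)
      expect_equal(call$branch_ok, branch_ok)
      expect_equal(call$call,
                   if (!donor_ok || !acc_ok || !branch_ok) "lost_motif"
                   else "putative")
    }
})

test_that("malformed intervals error", {
  expect_error(classify_species("ACGT", c(3, 2), "x"), "malformed")
  expect_error(classify_species("ACGT", c(0, 3), "x"), "malformed")
  expect_error(classify_species("ACGT", c(1, 10), "x"), "malformed")
})
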