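test_that("read_fasta uppercases, maps U to T and preserves record order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$residues, "ACGT")
  expect_equal(recs[[1]]$length, 4L)

  writeLines(c(">a", "ACGT", ">b", "uuuu"), f)
  recs <- read_fasta(f)
  expect_equal(names(recs), c("a", "b"))
  expect_equal(recs$b$residues, "TTTT")
})

test_that("read_fasta format errors name the problem", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "FASTA")
  writeLines(c(">a", "ACGT", ">a", "TT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">ok", "ACGT", ">bad", "ACQT"), f)
  expect_error(read_fasta(f), "bad.*non-IUPAC|non-IUPAC")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("FASTA round-trip reproduces sequences byte-identically", {
  set.seed(7)
  seqs <- lapply(1:5, function(i)
    genomic_sequence(paste0("s", i), rand_seq(sample(50:400, 1))))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "residues"),
               setNames(lapply(seqs, `[[`, "residues"),
                        vapply(seqs, `[[`, "", "id")))
})

test_that("gene_model validates its invariants", {
  ex <- data.frame(start = c(1, 50), end = c(20, 80))
  m <- gene_model("g", "s", "+", ex, 5)
  expect_s3_class(m, "gene_model")
  expect_error(gene_model("g", "s", "+", ex, 30), "cds_start")
  expect_error(gene_model("g", "s", "+",
                          data.frame(start = c(1, 15), end = c(20, 40)), 5),
               "overlap")
  expect_error(gene_model("g", "s", "+",
                          data.frame(start = 10, end = 5), 10), "end < start")
})

test_that("extract_mrna concatenates exons and records junctions", {
  s <- genomic_sequence("g", paste(rep("ACGTT", 20), collapse = ""))
  one <- gene_model("g", "g", "+", data.frame(start = 11, end = 40), 11)
  tx1 <- extract_mrna(s, one)
  expect_equal(tx1$junctions, integer(0))
  expect_equal(tx1$mrna, substr(s$residues, 11, 40))

  two <- gene_model("g", "g", "+",
                    data.frame(start = c(1, 31), end = c(10, 50)), 2)
  tx2 <- extract_mrna(s, two)
  expect_equal(tx2$junctions, 10L)
  expect_equal(nchar(tx2$mrna), 30L)

  bad <- gene_model("g", "g", "+", data.frame(start = 90, end = 150), 95)
  expect_error(extract_mrna(s, bad), "outside")
})

test_that("extract_mrna matches a cut-and-paste oracle on random genes", {
  set.seed(11)
  for (rep in 1:20) {
    g <- rand_seq(300)
    starts <- c(1L, 101L, 201L) + sample(0:20, 3)
    ends <- starts + sample(10:60, 3)
    seq <- genomic_sequence("r", g)
    model <- gene_model("r", "r", "+", data.frame(start = starts, end = ends),
                        starts[1])
    tx <- extract_mrna(seq, model)
    oracle <- paste(substring(g, starts, ends), collapse = "")
    expect_identical(tx$mrna, oracle)
    expect_equal(nchar(tx$mrna), sum(ends - starts + 1L))  # length conservation
  }
})

test_that("minus-strand extraction mirrors the plus strand", {
  set.seed(13)
  for (rep in 1:10) {
    g <- rand_seq(200)
    starts <- sort(sample(1:150, 2)); ends <- starts + c(20L, 30L)
    if (ends[1] >= starts[2]) next
    plus <- extract_mrna(
      genomic_sequence("p", g),
      gene_model("p", "p", "+", data.frame(start = starts, end = ends),
                 starts[1]))
    grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    n <- nchar(g)
    mstarts <- n - ends + 1L; mends <- n - starts + 1L
    minus <- extract_mrna(
      genomic_sequence("m", grc),
      gene_model("m", "m", "-", data.frame(start = mstarts, end = mends),
                 mends[1]))
    expect_identical(minus$mrna, plus$mrna)
  }
})

test_that("gene models survive the JSON dialect and GFF3 round trips", {
  m <- gene_model("gene1", "chr1",
                  "+", data.frame(start = c(10, 100), end = c(50, 160)), 20)
  jf <- withr::local_tempfile(fileext = ".json")
  write_gene_model_json(m, jf)
  m2 <- read_gene_model_json(jf)
  expect_equal(m2$exons, m$exons)
  expect_equal(m2$cds_start, m$cds_start)

  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t10\t160\t.\t+\t.\tID=gene1",
    "chr1\ttest\texon\t10\t50\t.\t+\t.\tParent=gene1",
    "chr1\ttest\texon\t100\t160\t.\t+\t.\tParent=gene1",
    "chr1\ttest\tCDS\t20\t50\t.\t+\t0\tParent=gene1",
    "chr1\ttest\tCDS\t100\t130\t.\t+\t0\tParent=gene1"), gf)
  m3 <- read_gene_model_gff3(gf)[["gene1"]]
  expect_equal(m3$exons$start, m$exons$start)
  expect_equal(m3$cds_start, 20L)
})

test_that("genomic_to_mrna maps exonic positions and rejects intronic ones", {
  s <- genomic_sequence("g", rand_seq(100))
  m <- gene_model("g", "g", "+",
                  data.frame(start = c(1, 51), end = c(20, 70)), 5)
  tx <- extract_mrna(s, m)
  expect_equal(genomic_to_mrna(tx, 1), 1L)
  expect_equal(genomic_to_mrna(tx, 51), 21L)
  expect_error(genomic_to_mrna(tx, 30), "not exonic")
})
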