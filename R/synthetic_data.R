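# Ground-truthed synthetic inputs. The generator emulates the architecture of
# the myostatin locus: a three-exon gene whose last exon carries a cryptic
# intron a few nt downstream of the intron 2/exon 3 boundary, whose excision
# appends a novel 3' coding segment (exon 3b) to the truncated propeptide
# frame. Background is i.i.d. nucleotides at a stated GC content (no
# higher-order structure) — sufficient to stress motif scanners, and a
# documented limitation.

SENSE_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]
# decoy-free coding alphabet: sense codons without G (cannot create GT or AG)
SENSE_CODONS_NOG <- SENSE_CODONS[!grepl("G", SENSE_CODONS)]
# codons not encoding a basic residue (K/R): used for the mature tail so the
# planted KERK is the most C-terminal convertase site, as in the emulated
# precursor where a single physiological cut is proposed
SENSE_CODONS_NO_BASIC <- SENSE_CODONS[!GENETIC_CODE_DNA[SENSE_CODONS] %in%
                                        c("K", "R")]

rand_dna <- function(n, gc = 0.42, alphabet = NULL) {
  if (n <= 0L) return("")
  if (is.null(alphabet)) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  } else {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  }
}

rand_codons <- function(k, pool = SENSE_CODONS) {
  if (k <= 0L) return(character(0))
  sample(pool, k, replace = TRUE)
}

#' Parameters of the synthetic planted-intron gene
#'
#' Defaults reproduce the published geometry of the myostatin splice variant:
#' a 1011-nt cryptic intron starting 21 nt into the last exon, a 198-nt novel
#' 3' coding segment (65 aa + stop), 747 nt of coding sequence on exons 1–2
#' (so the shared N-terminal domain is 768 nt = 256 codons), a GTAAG extended
#' donor, a TACTAAC-class branch point with its adenosine 25 nt upstream of
#' the acceptor, and a polypyrimidine tract of fraction ~0.93.
#'
#' @param gc Background GC content.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param exon12_coding Coding nt on exons 1 and 2 (each a multiple of 3).
#' @param exon3a_len Coding nt of exon 3 upstream of the cryptic intron.
#' @param cryptic_intron_len Planted intron length (nt, >= 60).
#' @param exon3b_len Novel 3' coding segment length incl. stop (multiple of 3).
#' @param intron_lens Lengths of the two real introns.
#' @param ppt_fraction Pyrimidine fraction planted in the 15-nt tract.
#' @param branch_offset Distance (nt) from the branch adenosine to the intron
#'   3' end (must lie in the scanning branch window).
#' @param plant_kerk Plant a KERK convertase motif at aa 271–274.
#' @param decoy_free Restrict background alphabets so the planted GT/AG pair
#'   is the only candidate pair in the gene (used for exactness tests).
#' @return A parameter list.
#' @export
synthetic_gene_params <- function(gc = 0.42, utr5_len = 60L, utr3_len = 150L,
                                  exon12_coding = c(372L, 375L),
                                  exon3a_len = 21L,
                                  cryptic_intron_len = 1011L,
                                  exon3b_len = 198L,
                                  intron_lens = c(200L, 200L),
                                  ppt_fraction = 14 / 15,
                                  branch_offset = 25L,
                                  plant_kerk = TRUE,
                                  decoy_free = FALSE) {
  stopifnot(exon12_coding %% 3 == 0, exon3b_len %% 3 == 0,
            cryptic_intron_len >= 60L, branch_offset >= 18L,
            branch_offset <= 40L, cryptic_intron_len > branch_offset + 12L)
  list(gc = gc, utr5_len = as.integer(utr5_len),
       utr3_len = as.integer(utr3_len),
       exon12_coding = as.integer(exon12_coding),
       exon3a_len = as.integer(exon3a_len),
       cryptic_intron_len = as.integer(cryptic_intron_len),
       exon3b_len = as.integer(exon3b_len),
       intron_lens = as.integer(intron_lens),
       ppt_fraction = ppt_fraction, branch_offset = as.integer(branch_offset),
       plant_kerk = isTRUE(plant_kerk), decoy_free = isTRUE(decoy_free))
}

build_cryptic_intron <- function(p) {
  L <- p$cryptic_intron_len
  ppt_len <- 15L
  n_pyr <- round(p$ppt_fraction * ppt_len)
  ppt <- sample(c(rep("T", ceiling(n_pyr / 2)), rep("C", floor(n_pyr / 2)),
                  rep("A", ppt_len - n_pyr)))
  if (p$decoy_free) ppt <- rep("T", ppt_len)
  b7_start <- L - p$branch_offset - 5L          # adenosine at position 6
  body_alpha <- if (p$decoy_free) c("A", "C") else NULL
  seg <- function(n) rand_dna(n, p$gc, body_alpha)
  body1 <- seg(b7_start - 6L)                    # between GTAAG and branch
  body2 <- seg(L - 17L - (b7_start + 6L))        # between branch and ppt
  intron <- paste0("GTAAG", body1, "TACTAAC", body2,
                   paste(ppt, collapse = ""), "AG")
  stopifnot(nchar(intron) == L)
  # canonical reading frame continues into the intron; plant an in-frame stop
  # so the unspliced transcript has a defined canonical ORF
  stop_codon_at <- min(360L, 3L * ((L - 3L) %/% 3L)) + 1L
  substr(intron, stop_codon_at, stop_codon_at + 2L) <- "TAA"
  intron
}

#' Generate a ground-truthed planted-intron gene
#'
#' @param params A [synthetic_gene_params()] list.
#' @param seed Integer seed; identical seed + params give byte-identical
#'   output.
#' @return A `planted_gene`: `sequence` ([genomic_sequence()]), `model`
#'   ([gene_model()]), and `truth` (planted intron interval and signals,
#'   ground-truth variant mRNA/ORF/protein, canonical protein, cleavage motif
#'   position), plus `params` and `seed`.
#' @export
make_gene <- function(params = synthetic_gene_params(), seed = 1L) {
  p <- params
  exon3_len <- p$exon3a_len + p$cryptic_intron_len + p$exon3b_len + p$utr3_len
  if (p$cryptic_intron_len > exon3_len - 2L) {
    stop("cryptic intron does not fit inside the host exon", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pool <- if (p$decoy_free) SENSE_CODONS_NOG else SENSE_CODONS
  n_prefix <- (sum(p$exon12_coding) + p$exon3a_len) / 3L   # shared codons
  stopifnot(n_prefix == as.integer(n_prefix))
  prefix <- c("ATG", rand_codons(n_prefix - 1L, pool))
  if (p$decoy_free) {
    # ATG ends in G: the following codon must not start with T (no GT) and
    # must not start with G (no ATG+G ambiguity is fine, but keep it simple)
    while (substr(prefix[2], 1L, 1L) %in% c("T", "G")) {
      prefix[2] <- sample(pool, 1L)
    }
  }
  n_3b <- p$exon3b_len / 3L                                # incl. stop codon
  codons_3b <- c(if (p$decoy_free) "AAT" else "GAT",       # != canonical GTA
                 rand_codons(n_3b - 2L, pool), "TAA")
  kerk_aa <- NULL
  if (p$plant_kerk && !p$decoy_free && n_3b >= 20L) {
    # KERK at precursor aa 271-274 = 3b codons 15-18 (shared prefix 256 aa)
    idx <- (271L:274L) - n_prefix                          # 3b codon indices
    if (all(idx >= 2L & idx <= n_3b - 1L)) {
      codons_3b[idx] <- c("AAA", "GAA", "CGT", "AAA")
      kerk_aa <- c(271L, 274L)
      # mature tail free of basic residues: KERK stays the last cleavage site
      tail_idx <- seq.int(max(idx) + 1L, n_3b - 1L)
      if (length(tail_idx)) {
        codons_3b[tail_idx] <- rand_codons(length(tail_idx),
                                           SENSE_CODONS_NO_BASIC)
      }
    }
  }

  utr_alpha <- if (p$decoy_free) c("A", "C", "T") else NULL
  utr5 <- rand_dna(p$utr5_len, p$gc, utr_alpha)
  utr3 <- rand_dna(p$utr3_len, p$gc, utr_alpha)
  n1 <- p$exon12_coding[1] / 3L
  coding1 <- paste(prefix[seq_len(n1)], collapse = "")
  coding2 <- paste(prefix[(n1 + 1L):(n1 + p$exon12_coding[2] / 3L)],
                   collapse = "")
  coding3a <- paste(prefix[(n1 + p$exon12_coding[2] / 3L + 1L):n_prefix],
                    collapse = "")
  intron_c <- build_cryptic_intron(p)
  exon3b <- paste(codons_3b, collapse = "")

  exon1 <- paste0(utr5, coding1)
  exon2 <- coding2
  exon3 <- paste0(coding3a, intron_c, exon3b, utr3)
  real_introns <- vapply(p$intron_lens, function(n)
    paste0("GT", rand_dna(n - 4L, p$gc), "AG"), "")

  genome <- paste0(exon1, real_introns[1], exon2, real_introns[2], exon3)
  e1 <- c(1L, nchar(exon1))
  e2 <- c(e1[2] + p$intron_lens[1] + 1L,
          e1[2] + p$intron_lens[1] + nchar(exon2))
  e3 <- c(e2[2] + p$intron_lens[2] + 1L,
          e2[2] + p$intron_lens[2] + nchar(exon3))
  seq <- genomic_sequence("synthetic_gene", genome)
  model <- gene_model("synthetic_gene", "synthetic_gene", "+",
                      data.frame(start = c(e1[1], e2[1], e3[1]),
                                 end = c(e1[2], e2[2], e3[2])),
                      cds_start = p$utr5_len + 1L)

  intron_start <- e3[1] + p$exon3a_len
  intron_end <- intron_start + p$cryptic_intron_len - 1L
  variant_mrna <- paste0(exon1, exon2, coding3a, exon3b, utr3)
  variant_cds <- paste0(paste(prefix, collapse = ""), exon3b)
  variant_protein <- translate_dna(substr(variant_cds, 1L,
                                          nchar(variant_cds) - 3L))
  canonical_mrna <- paste0(exon1, exon2, exon3)
  canonical_cds_region <- substr(canonical_mrna, p$utr5_len + 1L,
                                 nchar(canonical_mrna))
  nc <- nchar(canonical_cds_region) %/% 3L
  can_codons <- substring(canonical_cds_region, 3L * seq_len(nc) - 2L,
                          3L * seq_len(nc))
  can_stop <- which(can_codons %in% STOP_CODONS)[1]
  canonical_protein <- translate_dna(
    paste(can_codons[seq_len(can_stop - 1L)], collapse = ""))

  structure(list(
    sequence = seq, model = model,
    truth = list(
      intron_interval = c(intron_start, intron_end),
      donor_pos = intron_start, acceptor_pos = intron_end,
      branch_pos = intron_end - p$branch_offset - 5L,
      host_exon_index = 3L,
      exon3b_interval = c(intron_end + 1L, intron_end + p$exon3b_len),
      variant_mrna = variant_mrna,
      variant_orf_nt = nchar(variant_cds),
      variant_protein = variant_protein,
      canonical_protein = canonical_protein,
      kerk_aa = kerk_aa),
    params = p, seed = as.integer(seed)),
    class = "planted_gene")
}

#' @export
print.planted_gene <- function(x, ...) {
  cat(sprintf(
    "<planted_gene> %d nt, cryptic intron [%d,%d] (%d nt), variant ORF %d nt\n",
    x$sequence$length, x$truth$intron_interval[1], x$truth$intron_interval[2],
    diff(x$truth$intron_interval) + 1L, x$truth$variant_orf_nt))
  invisible(x)
}

ORTHOLOG_CLASSES <- c("none", "lost_motif_donor", "lost_motif_acceptor",
                      "lost_motif_branch", "premature_stop",
                      "frameshift_indel")

#' Generate an ortholog exon-3 set with specified lesions
#'
#' Each ortholog carries exactly the named lesion plus background
#' substitutions confined to the intron interior (where they cannot alter any
#' classification signal), and the expected conservation call is recorded as
#' ground truth.
#'
#' @param gene A [make_gene()] result.
#' @param degradations Named character vector, species -> class (one of
#'   `r paste(ORTHOLOG_CLASSES, collapse = ", ")`).
#' @param evidence Named character vector, species -> `"none"` (default) or
#'   `"confirmed_transcript"`.
#' @param subst_rate Background substitution rate in the intron interior.
#' @param seed Integer seed.
#' @return A list: `sequences` (named exon-3 DNA strings), `table`
#'   (input table for [classify_set()]), `truth` (expected calls).
#' @export
make_ortholog_set <- function(gene, degradations,
                              evidence = NULL, subst_rate = 0.01, seed = 1L) {
  stopifnot(inherits(gene, "planted_gene"))
  bad <- setdiff(degradations, ORTHOLOG_CLASSES)
  if (length(bad)) stop("unknown degradation class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  p <- gene$params
  ex <- gene$model$exons
  exon3 <- substr(gene$sequence$residues, ex$start[3], ex$end[3])
  i1 <- p$exon3a_len + 1L                       # intron start, exon-local
  i2 <- i1 + p$cryptic_intron_len - 1L
  L <- p$cryptic_intron_len
  ref_spliced_len <- nchar(exon3) - L
  ref_orf_codons <- (p$exon3a_len + p$exon3b_len) / 3L  # index of stop codon

  species <- names(degradations)
  ev_of <- function(sp) {
    if (!is.null(evidence) && sp %in% names(evidence)) evidence[[sp]]
    else "none"
  }
  seqs <- character(0); truth <- list(); rows <- list()
  for (sp in species) {
    s <- exon3
    cls <- degradations[[sp]]
    # background substitutions: intron interior only, clear of the donor,
    # branch region and polypyrimidine tract
    safe <- seq.int(i1 + 6L, i1 + L - 52L)
    nmut <- stats::rbinom(1L, length(safe), subst_rate)
    if (nmut > 0L) {
      at <- sample(safe, nmut)
      for (pos in at) {
        cur <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    expected <- switch(cls,
      none = if (ev_of(sp) == "confirmed_transcript") "fixed" else "putative",
      lost_motif_donor = , lost_motif_acceptor = ,
      lost_motif_branch = "lost_motif",
      premature_stop = , frameshift_indel = "lost_orf")
    if (cls == "lost_motif_donor") substr(s, i1 + 1L, i1 + 1L) <- "C"
    if (cls == "lost_motif_acceptor") substr(s, i2, i2) <- "C"
    if (cls == "lost_motif_branch") {
      # any branch 7-mer scoring in the window must have its adenosine in
      # [i2 - 40, i2 - 18]; G-fill that stretch so no match survives
      substr(s, i2 - 40L, i2 - 18L) <-
        paste(rep("G", 23L), collapse = "")
    }
    # a codon a few positions into exon 3b, well before the reference stop
    k_3b <- p$exon3a_len %/% 3L + 6L
    if (cls == "premature_stop") {
      pos <- 3L * (k_3b - 1L) + 1L + L          # unspliced exon-3 coordinate
      substr(s, pos, pos + 2L) <- "TAA"
    }
    if (cls == "frameshift_indel") {
      pos <- 3L * k_3b + 1L + L                 # 1-nt deletion in exon 3b
      s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, nchar(s)))
    }
    seqs[[sp]] <- s
    rows[[sp]] <- data.frame(species = sp, intron_start = i1, intron_end = i2,
                             evidence = ev_of(sp), frame_offset = 0L,
                             reference_spliced_length = ref_spliced_len,
                             reference_orf_codons = ref_orf_codons,
                             stringsAsFactors = FALSE)
    truth[[sp]] <- data.frame(species = sp, class = cls, call = expected,
                              stringsAsFactors = FALSE)
  }
  list(sequences = seqs, table = do.call(rbind, rows),
       truth = do.call(rbind, truth))
}
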