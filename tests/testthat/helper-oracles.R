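# Independent brute-force oracles. These deliberately re-derive each rule by
# direct enumeration, sharing no code with the implementation they check.

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# every 1-based window start where the IUPAC pattern matches, by per-position
# set membership (an N in the subject matches nothing)
oracle_iupac_match <- function(subject, pattern) {
  sv <- strsplit(subject, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  k <- length(pv)
  hits <- integer(0)
  for (i in seq_len(max(0L, length(sv) - k + 1L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sv[i + j - 1L] %in% IUPAC_SET[[pv[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_branch_matches <- function(window) oracle_iupac_match(window, "YNYTRAY")

# all convertase consensus matches by direct double loop
oracle_convertase <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  L <- length(aa)
  out <- NULL
  for (i in seq_len(L)) {
    for (n in c(0L, 2L, 4L, 6L)) {
      j <- i + n + 1L
      if (j > L) next
      if (!(aa[i] %in% c("K", "R")) || !(aa[j] %in% c("K", "R"))) next
      if (n > 0L && any(aa[(i + 1L):(j - 1L)] == "C")) next
      out <- rbind(out, data.frame(start_aa = i, end_aa = j, spacer_n = n))
    }
  }
  if (is.null(out)) data.frame(start_aa = integer(0), end_aa = integer(0),
                               spacer_n = integer(0)) else out
}

# digestion by enumerating every recognition-site window, then cutting
oracle_digest_lengths <- function(s, pattern, cut_offset) {
  hits <- oracle_iupac_match(s, pattern)
  cuts <- sort(unique(hits + cut_offset - 1L))
  cuts <- cuts[cuts >= 1L & cuts < nchar(s)]
  diff(c(0L, cuts, nchar(s)))
}

# codon-walk ORF oracle: returns list(orf_nt, protein) from a 1-based start
oracle_orf <- function(mrna, start) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  i <- start
  aa <- character(0)
  while (i + 2L <= nchar(mrna)) {
    codon <- substr(mrna, i, i + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      return(list(orf_nt = i + 2L - start + 1L,
                  protein = paste(aa, collapse = ""), stopped = TRUE))
    }
    aa <- c(aa, unname(code[codon]))
    i <- i + 3L
  }
  list(orf_nt = length(aa) * 3L, protein = paste(aa, collapse = ""),
       stopped = FALSE)
}

# GT x AG pairing oracle for the completeness property (no signal filters):
# counts pairs within length bounds leaving >=1 nt of flanking exon
oracle_pair_count <- function(exon_seq, min_len, max_len) {
  donors <- oracle_iupac_match(exon_seq, "GT")
  donors <- donors[donors >= 2L]
  acceptors <- oracle_iupac_match(exon_seq, "AG") + 1L
  acceptors <- acceptors[acceptors <= nchar(exon_seq) - 1L]
  n <- 0L
  for (i in donors) for (j in acceptors) {
    len <- j - i + 1L
    if (len >= min_len && len <= max_len) n <- n + 1L
  }
  n
}

# a single-exon gene around an mRNA string, for isoform tests
toy_transcript <- function(mrna, cds_start = 1L) {
  seq <- genomic_sequence("toy", mrna)
  model <- gene_model("toy", "toy", "+",
                      data.frame(start = 1L, end = nchar(mrna)), cds_start)
  extract_mrna(seq, model)
}
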