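# Cryptic-intron discovery inside annotated exons.
#
# The grammar is the minimal metazoan one: a GT donor, an AG acceptor, a
# YNYTRAY branch point whose adenosine sits in a window upstream of the
# acceptor, and a polypyrimidine tract immediately upstream of the acceptor
# AG. Scanning is performed on the coding strand only.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  cls <- IUPAC_CLASSES[chars]
  if (anyNA(cls)) stop("unknown IUPAC code in pattern: ", pattern, call. = FALSE)
  paste0(vapply(cls, function(x)
    if (nchar(x) == 1L) x else paste0("[", x, "]"), ""), collapse = "")
}

# All 1-based start positions of an IUPAC pattern in a DNA string, overlaps
# included. An N in the subject never matches (conservative on draft sequence).
iupac_match <- function(subject, pattern) {
  rx <- iupac_regex(pattern)
  m <- gregexpr(paste0("(?=", rx, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Splice-signal profile
#'
#' Bundles the tunable parameters of the cryptic-intron grammar. The branch
#' window is the distance (nt) from the branch-point adenosine to the intron's
#' 3' end; the polypyrimidine window is the stretch immediately upstream of the
#' acceptor AG.
#'
#' @param donor,acceptor Terminal dinucleotides (canonical GT/AG).
#' @param branch_consensus IUPAC 7-mer, default `"YNYTRAY"`.
#' @param branch_window Integer range, distance of the branch A from the intron
#'   3' end; default `c(18, 40)`.
#' @param ppt_window Length (nt) of the polypyrimidine window, default 15.
#' @param ppt_min_fraction Minimum pyrimidine fraction, default 0.6. Setting it
#'   to 0 disables the polypyrimidine filter.
#' @param min_intron_len,max_intron_len Candidate length bounds (default
#'   60–10000 nt).
#' @param require_branch Require a branch-point match (default TRUE).
#' @return A `splice_profile` object.
#' @export
splice_profile <- function(donor = "GT", acceptor = "AG",
                           branch_consensus = "YNYTRAY",
                           branch_window = c(18L, 40L),
                           ppt_window = 15L, ppt_min_fraction = 0.6,
                           min_intron_len = 60L, max_intron_len = 10000L,
                           require_branch = TRUE) {
  stopifnot(ppt_window > 0, ppt_min_fraction >= 0, ppt_min_fraction <= 1,
            min_intron_len <= max_intron_len, min_intron_len > 0,
            length(branch_window) == 2L, all(branch_window > 0),
            branch_window[1] <= branch_window[2])
  structure(list(donor = donor, acceptor = acceptor,
                 branch_consensus = branch_consensus,
                 branch_window = as.integer(branch_window),
                 ppt_window = as.integer(ppt_window),
                 ppt_min_fraction = ppt_min_fraction,
                 min_intron_len = as.integer(min_intron_len),
                 max_intron_len = as.integer(max_intron_len),
                 require_branch = isTRUE(require_branch)),
            class = "splice_profile")
}

#' Find branch-point consensus matches in a window
#'
#' Reports every 1-based start position where the 7-mer satisfies the
#' positional rule Y-N-Y-T-R-A-Y (Y = C/T, R = A/G, N = any of A/C/G/T). A
#' window containing `N` at a constrained position does not match.
#'
#' @param window DNA string over \{A,C,G,T,N\}.
#' @param consensus IUPAC pattern (default `"YNYTRAY"`).
#' @return A data.frame with columns `start` (1-based) and `match` (the 7-mer);
#'   zero rows when there is no match.
#' @export
match_branch_point <- function(window, consensus = "YNYTRAY") {
  window <- toupper(window)
  starts <- iupac_match(window, consensus)
  if (!length(starts)) {
    return(data.frame(start = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(start = starts,
             match = substring(window, starts, starts + nchar(consensus) - 1L),
             stringsAsFactors = FALSE)
}

pyrimidine_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  if (grepl("N", s, fixed = TRUE)) return(NA_real_)
  (n - nchar(gsub("[CT]", "", s))) / n
}

# Scan one exon-local sequence. Returns candidates in exon-local 1-based
# coordinates: donor_local = first nt of the intron, acceptor_local = last nt.
scan_exon_local <- function(s, profile) {
  m <- nchar(s)
  empty <- data.frame(donor_local = integer(0), acceptor_local = integer(0),
                      length = integer(0), branch_local = integer(0),
                      ppt_fraction = numeric(0), score = numeric(0))
  if (m < profile$min_intron_len + 2L) return(NULL)  # caller logs the skip
  donors <- iupac_match(s, profile$donor)
  donors <- donors[donors >= 2L]                     # >=1 nt 5' flanking exon
  acc_end <- iupac_match(s, profile$acceptor) + nchar(profile$acceptor) - 1L
  acc_end <- acc_end[acc_end <= m - 1L]              # >=1 nt 3' flanking exon
  if (!length(donors) || !length(acc_end)) return(empty)

  branch_starts <- iupac_match(s, profile$branch_consensus)
  branch_A <- branch_starts + 5L  # consensus position 6 is the adenosine

  # per-acceptor signals (position of ppt/branch depends only on the acceptor)
  ppt_start <- acc_end - 2L - profile$ppt_window + 1L
  ppt_frac <- vapply(seq_along(acc_end), function(k) {
    if (ppt_start[k] < 1L) return(NA_real_)
    pyrimidine_fraction(substr(s, ppt_start[k], acc_end[k] - 2L))
  }, 0)
  branch_for_acc <- lapply(acc_end, function(j) {
    d <- j - branch_A
    branch_starts[d >= profile$branch_window[1] & d <= profile$branch_window[2]]
  })

  res <- vector("list", length(acc_end))
  for (k in seq_along(acc_end)) {
    j <- acc_end[k]
    len <- j - donors + 1L
    keep <- len >= profile$min_intron_len & len <= profile$max_intron_len
    i <- donors[keep]
    if (!length(i)) next
    # filters (skipped entirely when disabled, so completeness is exact)
    frac <- ppt_frac[k]
    if (profile$ppt_min_fraction > 0) {
      ok <- !is.na(frac) && frac >= profile$ppt_min_fraction &&
        ppt_start[k] > min(i) + 1L  # at least one donor leaves ppt intronic
      if (!ok) next
      i <- i[ppt_start[k] > i + 1L]  # ppt fully inside the intron
      if (!length(i)) next
    }
    br <- branch_for_acc[[k]]
    if (profile$require_branch) {
      if (!length(br)) next
      # branch 7-mer fully inside the intron, downstream of the donor GT
      bsel <- function(i0) br[br >= i0 + 2L]
      has_br <- vapply(i, function(i0) length(bsel(i0)) > 0L, NA)
      i <- i[has_br]
      if (!length(i)) next
      bpos <- vapply(i, function(i0) min(bsel(i0)), 0L)
    } else {
      bpos <- vapply(i, function(i0) {
        v <- br[br >= i0 + 2L]
        if (length(v)) min(v) else NA_integer_
      }, 0L)
    }
    donor_bonus <- as.numeric(substring(s, i, i + 4L) == "GTAAG") * 0.1
    frac_used <- if (is.na(frac)) 0 else frac
    score <- frac_used + as.numeric(!is.na(bpos)) + donor_bonus
    res[[k]] <- data.frame(donor_local = i, acceptor_local = j,
                           length = j - i + 1L, branch_local = bpos,
                           ppt_fraction = frac, score = score)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, NA)])
  if (is.null(out)) empty else out
}

#' Scan a gene's exons for cryptic-intron candidates
#'
#' Every GT...AG pair inside a single exon within the profile's length bounds
#' is evaluated; candidates whose removal would not leave at least 1 nt of
#' flanking exon on both sides, or that fail the polypyrimidine/branch-point
#' filters, are excluded. Survivors are sorted by descending composite score
#' (pyrimidine fraction + 1 for a branch-point match + 0.1 for a GTAAG
#' extended donor), ties broken by 5'-most donor, then shorter length.
#'
#' @param seq A [genomic_sequence()].
#' @param model A [gene_model()] on that sequence.
#' @param profile A [splice_profile()].
#' @return A data.frame of candidates with genomic (1-based, coding strand)
#'   and exon-local coordinates.
#' @export
scan_cryptic_introns <- function(seq, model, profile = splice_profile()) {
  stopifnot(inherits(seq, "genomic_sequence"), inherits(model, "gene_model"))
  ex <- model$exons
  all <- vector("list", nrow(ex))
  for (e in seq_len(nrow(ex))) {
    s <- substr(seq$residues, ex$start[e], ex$end[e])
    if (model$strand == "-") s <- revcomp(s)
    cand <- scan_exon_local(s, profile)
    if (is.null(cand)) {
      message("exon ", e, " shorter than min_intron_len + 2; skipped")
      next
    }
    if (!nrow(cand)) next
    cand$host_exon_index <- e
    # exon-local -> genomic (coding strand positions)
    to_g <- if (model$strand == "+") function(p) ex$start[e] + p - 1L
            else function(p) ex$end[e] - p + 1L
    cand$donor_pos <- to_g(cand$donor_local)
    cand$acceptor_pos <- to_g(cand$acceptor_local)
    cand$branch_pos <- ifelse(is.na(cand$branch_local), NA_integer_,
                              to_g(cand$branch_local))
    cand$intron_start <- pmin(cand$donor_pos, cand$acceptor_pos)
    cand$intron_end <- pmax(cand$donor_pos, cand$acceptor_pos)
    all[[e]] <- cand
  }
  out <- do.call(rbind, all[!vapply(all, is.null, NA)])
  if (is.null(out)) {
    out <- data.frame(host_exon_index = integer(0), donor_pos = integer(0),
                      acceptor_pos = integer(0), intron_start = integer(0),
                      intron_end = integer(0), length = integer(0),
                      branch_pos = integer(0), ppt_fraction = numeric(0),
                      score = numeric(0), donor_local = integer(0),
                      acceptor_local = integer(0), branch_local = integer(0))
    return(out)
  }
  # tie-break: 5'-most donor first, then shorter length. A chance extended
  # donor nested inside a true intron shares its acceptor-side signals and
  # ties the composite score; preferring the 5'-most donor resolves the tie
  # toward the biologically used site.
  out <- out[order(-out$score, out$donor_local, out$length), ]
  rownames(out) <- NULL
  out[, c("host_exon_index", "donor_pos", "acceptor_pos", "intron_start",
          "intron_end", "length", "branch_pos", "ppt_fraction", "score",
          "donor_local", "acceptor_local", "branch_local")]
}

#' Write candidates as BED6
#'
#' Intervals are converted to 0-based half-open; the score column is the
#' composite score scaled to 0–1000 (2.1 -> 1000).
#'
#' @param candidates Output of [scan_cryptic_introns()].
#' @param seq_id Chromosome/sequence name for column 1.
#' @param path Output path.
#' @export
write_candidates_bed <- function(candidates, seq_id, path) {
  bed <- data.frame(
    chrom = seq_id,
    start = candidates$intron_start - 1L,
    end = candidates$intron_end,
    name = sprintf("cryptic_intron_%d", seq_len(nrow(candidates))),
    score = as.integer(round(pmin(candidates$score / 2.1, 1) * 1000)),
    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write candidates as TSV (all fields)
#' @param candidates Output of [scan_cryptic_introns()].
#' @param path Output path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
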