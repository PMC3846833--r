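# In-silico splicing of a candidate intron, ORF reconstruction, and the
# 50-nt NMD rule.

#' Splice a cryptic-intron candidate out of a transcript
#'
#' Removes the candidate interval from the mRNA, inserts a new exon/exon
#' junction at the fusion point and updates the genomic-to-mRNA segment map.
#'
#' @param transcript A [extract_mrna()] transcript.
#' @param candidate One row of [scan_cryptic_introns()] output (or any list
#'   with `intron_start`, `intron_end` in genomic coordinates).
#' @return A new `transcript`, shorter by the intron length.
#' @export
splice_candidate <- function(transcript, candidate) {
  stopifnot(inherits(transcript, "transcript"))
  g1 <- as.integer(candidate$intron_start)
  g2 <- as.integer(candidate$intron_end)
  seg <- transcript$segments
  host <- which(g1 >= seg$g_start & g2 <= seg$g_end)
  if (!length(host)) {
    stop("candidate interval [", g1, ",", g2,
         "] is not contained in a single exon segment", call. = FALSE)
  }
  host <- host[1]
  minus <- transcript$source_model$strand == "-"
  m1 <- genomic_to_mrna(transcript, if (minus) g2 else g1)
  m2 <- genomic_to_mrna(transcript, if (minus) g1 else g2)
  stopifnot(m2 >= m1)
  len <- m2 - m1 + 1L
  if (m1 <= seg$m_start[host] || m2 >= seg$m_end[host]) {
    stop("splicing would remove an entire exon end; not a cryptic intron",
         call. = FALSE)
  }
  mrna <- paste0(substr(transcript$mrna, 1L, m1 - 1L),
                 substr(transcript$mrna, m2 + 1L, nchar(transcript$mrna)))
  # split the host segment at the intron
  left <- seg[host, ]; right <- seg[host, ]
  if (!minus) {
    left$g_end <- g1 - 1L; right$g_start <- g2 + 1L
  } else {
    left$g_start <- g2 + 1L; right$g_end <- g1 - 1L
  }
  left$m_end <- m1 - 1L
  right$m_start <- m1; right$m_end <- seg$m_end[host] - len
  after <- seg[seq_len(nrow(seg)) > host, , drop = FALSE]
  if (nrow(after)) {
    after$m_start <- after$m_start - len; after$m_end <- after$m_end - len
  }
  segments <- rbind(seg[seq_len(nrow(seg)) < host, , drop = FALSE],
                    left, right, after)
  rownames(segments) <- NULL
  junctions <- sort(unique(c(
    ifelse(transcript$junctions > m1 - 1L,
           transcript$junctions - len, transcript$junctions),
    m1 - 1L)))
  spliced <- rbind(transcript$spliced_introns,
                   data.frame(start = g1, end = g2))
  structure(list(mrna = mrna, junctions = as.integer(junctions),
                 segments = segments,
                 source_model = transcript$source_model,
                 spliced_introns = spliced),
            class = "transcript")
}

GENETIC_CODE_DNA <- {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), gsub("U", "T", names(gc)))
}

translate_dna <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_DNA[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate and translate the ORF of a transcript
#'
#' Reads codons from the chosen start to the first in-frame stop and translates
#' them with the standard genetic code. With `start_policy = "annotated_atg"`
#' the start is the gene model's `cds_start` mapped onto the (possibly
#' cryptically spliced) mRNA; `"first_atg"` uses the 5'-most ATG.
#'
#' @param transcript A `transcript`.
#' @param start_policy `"annotated_atg"` (default) or `"first_atg"`.
#' @return An `isoform_record`: the transcript plus `orf_start` (0-based mRNA
#'   offset), `orf_stop` (0-based offset one past the terminating codon),
#'   `orf_length_nt`, `protein`, `run_through`, and the NMD fields
#'   `nmd_flag`/`ptc_distance` filled in by [nmd_check()].
#' @export
find_orf <- function(transcript,
                     start_policy = c("annotated_atg", "first_atg")) {
  start_policy <- match.arg(start_policy)
  mrna <- transcript$mrna
  if (start_policy == "annotated_atg") {
    m <- genomic_to_mrna(transcript, transcript$source_model$cds_start)
  } else {
    m <- as.integer(regexpr("ATG", mrna, fixed = TRUE))
    if (m < 0L) stop("no ATG in mRNA", call. = FALSE)
  }
  if (substr(mrna, m, m + 2L) != "ATG") {
    stop("mRNA does not carry ATG at the chosen start (position ", m, ")",
         call. = FALSE)
  }
  n_codons <- (nchar(mrna) - m + 1L) %/% 3L
  codons <- substring(mrna, m + 3L * (seq_len(n_codons) - 1L),
                      m + 3L * seq_len(n_codons) - 1L)
  stop_idx <- which(codons %in% STOP_CODONS)
  run_through <- length(stop_idx) == 0L
  k <- if (run_through) n_codons else stop_idx[1]
  orf_len <- 3L * k
  protein <- translate_dna(paste(codons[seq_len(if (run_through) k else k - 1L)],
                                 collapse = ""))
  rec <- structure(list(
    transcript = transcript,
    orf_start = m - 1L,                       # 0-based
    orf_stop = m - 1L + orf_len,              # 0-based, one past the stop
    orf_length_nt = orf_len,
    protein = protein,
    run_through = run_through,
    nmd_flag = NA, ptc_distance = NA_integer_),
    class = "isoform_record")
  if (!run_through) rec <- nmd_check(rec) else rec$nmd_flag <- NA
  rec
}

#' @export
print.isoform_record <- function(x, ...) {
  cat(sprintf("<isoform_record> ORF %d nt (%d aa)%s; NMD: %s (ptc_distance %s)\n",
              x$orf_length_nt, nchar(x$protein),
              if (x$run_through) " [run-through]" else "",
              x$nmd_flag, x$ptc_distance))
  invisible(x)
}

#' Apply the 50-nt NMD rule
#'
#' An mRNA is flagged for nonsense-mediated decay when its stop codon ends
#' more than 50 nt upstream of the final exon/exon junction. `ptc_distance` is
#' the distance from the end of the stop codon to that junction (negative when
#' the stop lies downstream of it; `NA` for junction-less transcripts, which
#' are never flagged).
#'
#' @param record An `isoform_record`.
#' @return The record with `nmd_flag` and `ptc_distance` set.
#' @export
nmd_check <- function(record) {
  stopifnot(inherits(record, "isoform_record"))
  j <- record$transcript$junctions
  if (!length(j)) {
    record$ptc_distance <- NA_integer_
    record$nmd_flag <- FALSE
    return(record)
  }
  final_junction <- max(j)
  record$ptc_distance <- as.integer(final_junction - record$orf_stop)
  record$nmd_flag <- record$ptc_distance > 50L
  record
}
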