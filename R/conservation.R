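# Per-species classification of cryptic-intron conservation from the motif /
# ORF integrity rule table. Homologous intron coordinates come from a user
# alignment; multiple alignment itself is out of scope.

#' Classify the conservation state of the splicing event in one species
#'
#' Motif flags are evaluated at the stated positions of the homologous intron
#' (`donor_ok`: intron starts with GT; `acceptor_ok`: intron ends with AG;
#' `branch_ok`: a branch-point consensus match whose adenosine lies within the
#' profile's branch window of the intron 3' end). The ORF status is evaluated
#' on the in-silico spliced product, reading codons from `frame_offset`:
#' `frameshift_indel` when the spliced length differs from
#' `reference_spliced_length` by a non-multiple of 3; `premature_stop` when the
#' first in-frame stop falls before codon `reference_orf_codons`; `intact`
#' otherwise (a stop at or beyond the reference stop codon, including
#' read-through, is not a loss).
#'
#' The call follows the rule table: `lost_motif` iff any motif flag is false;
#' otherwise `lost_orf` iff the ORF is not intact; otherwise `fixed` when
#' transcript evidence exists, else `putative`.
#'
#' @param exon3_seq DNA string of the exon-3 homolog.
#' @param intron_interval `c(start, end)` of the homologous cryptic intron
#'   (1-based inclusive, local to `exon3_seq`).
#' @param species Species label.
#' @param evidence `"none"` or `"confirmed_transcript"`.
#' @param profile A [splice_profile()] (branch window/consensus used).
#' @param frame_offset nt of `exon3_seq` before the first complete codon
#'   (0, 1 or 2).
#' @param reference_spliced_length Spliced exon-3 length of the reference
#'   species (frameshift detection); `NULL` disables the indel check.
#' @param reference_orf_codons 1-based codon index of the reference stop codon
#'   within the spliced exon-3 frame; `NULL` means any in-frame stop before the
#'   end of the sequence counts as intact.
#' @return A one-row data.frame (`conservation_call`): `species`, `donor_ok`,
#'   `acceptor_ok`, `branch_ok`, `orf_status`, `call`.
#' @export
classify_species <- function(exon3_seq, intron_interval, species,
                             evidence = c("none", "confirmed_transcript"),
                             profile = splice_profile(),
                             frame_offset = 0L,
                             reference_spliced_length = NULL,
                             reference_orf_codons = NULL) {
  evidence <- match.arg(evidence)
  s <- toupper(exon3_seq)
  i1 <- as.integer(intron_interval[1]); i2 <- as.integer(intron_interval[2])
  if (is.na(i1) || is.na(i2) || i1 < 1L || i2 > nchar(s) || i2 <= i1) {
    stop("malformed intron interval [", i1, ",", i2, "] for ", species,
         call. = FALSE)
  }
  donor_ok <- substr(s, i1, i1 + 1L) == profile$donor
  acceptor_ok <- substr(s, i2 - 1L, i2) == profile$acceptor
  intron <- substr(s, i1, i2)
  bm <- match_branch_point(intron, profile$branch_consensus)
  dist <- nchar(intron) - (bm$start + 5L)  # adenosine to intron 3' end
  branch_ok <- any(dist >= profile$branch_window[1] &
                     dist <= profile$branch_window[2])

  spliced <- paste0(substr(s, 1L, i1 - 1L), substr(s, i2 + 1L, nchar(s)))
  orf_status <- "intact"
  if (!is.null(reference_spliced_length) &&
      (nchar(spliced) - reference_spliced_length) %% 3L != 0L) {
    orf_status <- "frameshift_indel"
  } else {
    coding <- substr(spliced, frame_offset + 1L, nchar(spliced))
    n <- nchar(coding) %/% 3L
    codons <- substring(coding, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    first_stop <- which(codons %in% STOP_CODONS)[1]
    ref_k <- if (is.null(reference_orf_codons)) n else reference_orf_codons
    if (!is.na(first_stop) && first_stop < ref_k) orf_status <- "premature_stop"
  }

  call <- if (!donor_ok || !acceptor_ok || !branch_ok) "lost_motif"
          else if (orf_status != "intact") "lost_orf"
          else if (evidence == "confirmed_transcript") "fixed"
          else "putative"
  data.frame(species = species, donor_ok = donor_ok, acceptor_ok = acceptor_ok,
             branch_ok = branch_ok, orf_status = orf_status, call = call,
             stringsAsFactors = FALSE)
}

#' Classify a set of ortholog exon-3 sequences
#'
#' @param sequences Named character vector (or list of [genomic_sequence()])
#'   of exon-3 homologs.
#' @param table Data.frame with one row per species: `species`,
#'   `intron_start`, `intron_end`, `evidence`, and optionally `frame_offset`,
#'   `reference_spliced_length`, `reference_orf_codons`.
#' @param profile A [splice_profile()].
#' @return A data.frame of per-species conservation calls.
#' @export
classify_set <- function(sequences, table, profile = splice_profile()) {
  if (is.list(sequences) && inherits(sequences[[1]], "genomic_sequence")) {
    sequences <- vapply(sequences, `[[`, "", "residues") |>
      setNames(vapply(sequences, `[[`, "", "id"))
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    classify_species(
      sequences[[r$species]], c(r$intron_start, r$intron_end), r$species,
      evidence = r$evidence, profile = profile,
      frame_offset = if ("frame_offset" %in% names(r)) r$frame_offset else 0L,
      reference_spliced_length =
        if ("reference_spliced_length" %in% names(r))
          r$reference_spliced_length else NULL,
      reference_orf_codons =
        if ("reference_orf_codons" %in% names(r))
          r$reference_orf_codons else NULL)
  })
  do.call(rbind, rows)
}
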