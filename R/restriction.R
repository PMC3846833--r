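# Restriction digestion and probe hybridization (in-silico Southern).
# Fragment lengths use top-strand cut positions only; the blunt/overhang
# distinction is ignored at the gel-level size resolution targeted here.

#' Bundled restriction enzyme table
#'
#' Standard REBASE definitions of the three enzymes used for the myostatin
#' locus Southern: BclI `T^GATCA`, EcoRI `G^AATTC`, HincII `GTY^RAC`.
#' `cut_offset` counts nt from the start of the recognition pattern to the
#' top-strand cut.
#'
#' @return A data.frame with columns `name`, `recognition`, `cut_offset`.
#' @export
enzymes <- function() {
  data.frame(name = c("BclI", "EcoRI", "HincII"),
             recognition = c("TGATCA", "GAATTC", "GTYRAC"),
             cut_offset = c(1L, 1L, 3L),
             stringsAsFactors = FALSE)
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC DNA pattern.
#' @param cut_offset nt from the pattern start to the top-strand cut
#'   (0 <= `cut_offset` <= pattern length).
#' @return A one-row enzyme data.frame; a note is logged when the recognition
#'   pattern is not palindromic (not enforced).
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  cut_offset <- as.integer(cut_offset)
  stopifnot(cut_offset >= 0L, cut_offset <= nchar(recognition))
  rc <- revcomp_iupac(recognition)
  if (rc != recognition) {
    message("enzyme ", name, ": recognition pattern ", recognition,
            " is not palindromic")
  }
  data.frame(name = name, recognition = recognition, cut_offset = cut_offset,
             stringsAsFactors = FALSE)
}

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

revcomp_iupac <- function(pattern) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(toupper(pattern), "")[[1]]]),
        collapse = "")
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Cuts at every IUPAC match of the recognition pattern on the top strand at
#' the enzyme's `cut_offset`. A sequence without a site yields a single
#' full-length fragment (not an error). Fragments tile the sequence.
#'
#' @param seq A [genomic_sequence()] or a DNA string.
#' @param enzyme One row of [enzymes()] (or [enzyme()]).
#' @return A `fragment_set`: list with `fragments` (data.frame `start`, `end`,
#'   `length`, 1-based inclusive), `enzyme`, `seq_length`.
#' @export
digest <- function(seq, enzyme) {
  s <- if (inherits(seq, "genomic_sequence")) seq$residues else toupper(seq)
  n <- nchar(s)
  hits <- iupac_match(s, enzyme$recognition)
  cuts <- hits + enzyme$cut_offset - 1L          # cut after this position
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  bounds <- c(0L, cuts, n)
  frags <- data.frame(start = head(bounds, -1L) + 1L, end = bounds[-1])
  frags$length <- frags$end - frags$start + 1L
  structure(list(fragments = frags, enzyme = enzyme$name, seq_length = n),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s: %d fragment(s) of %d nt total\n",
              x$enzyme, nrow(x$fragments), x$seq_length))
  invisible(x)
}

#' Fragments detected by a labeled probe
#'
#' @param fragset A [digest()] result.
#' @param probe_interval Genomic interval `c(start, end)` (1-based inclusive)
#'   on the same coordinates as the fragments.
#' @return The fragment data.frame with a logical `probe_hit` column; a probe
#'   entirely outside the sequence yields no hits with a warning.
#' @export
probe_fragments <- function(fragset, probe_interval) {
  stopifnot(inherits(fragset, "fragment_set"), length(probe_interval) == 2L)
  p1 <- probe_interval[1]; p2 <- probe_interval[2]
  fr <- fragset$fragments
  if (p2 < 1L || p1 > fragset$seq_length) {
    warning("probe interval outside sequence; no fragments hit")
    fr$probe_hit <- FALSE
    return(fr)
  }
  fr$probe_hit <- fr$end >= p1 & fr$start <= p2   # >=1 nt overlap
  fr
}

#' Map a cDNA probe onto a genome by exact substring match
#'
#' The exon 1–2 probe of the myostatin Southern is identical between cDNA and
#' genome, so an exact match suffices (per design; no alignment).
#'
#' @param genome A [genomic_sequence()].
#' @param probe_seq Probe DNA string.
#' @return `c(start, end)` of the unique exact match; errors when absent or
#'   ambiguous.
#' @export
map_probe <- function(genome, probe_seq) {
  m <- gregexpr(toupper(probe_seq), genome$residues, fixed = TRUE)[[1]]
  if (m[1] == -1L) stop("probe has no exact match in ", genome$id, call. = FALSE)
  if (length(m) > 1L) stop("probe matches ", genome$id, " more than once",
                           call. = FALSE)
  c(as.integer(m), as.integer(m) + nchar(probe_seq) - 1L)
}

#' Digest with several enzymes and report probe hits
#'
#' @param seq A [genomic_sequence()].
#' @param enzyme_table Data.frame like [enzymes()].
#' @param probe_interval Optional probe interval for [probe_fragments()].
#' @return A data.frame: `enzyme`, `start`, `end`, `length`, `probe_hit`.
#' @export
digest_report <- function(seq, enzyme_table = enzymes(),
                          probe_interval = NULL) {
  rows <- lapply(seq_len(nrow(enzyme_table)), function(i) {
    fs <- digest(seq, enzyme_table[i, ])
    fr <- if (is.null(probe_interval)) {
      cbind(fs$fragments, probe_hit = NA)
    } else probe_fragments(fs, probe_interval)
    cbind(enzyme = enzyme_table$name[i], fr)
  })
  do.call(rbind, rows)
}
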