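# Protein-level annotation: proprotein convertase / furin cleavage motifs,
# molecular weights, shared-prefix identity and the cysteine census.

# Average and monoisotopic residue masses (Da) of the 20 standard amino acids
# (residue = amino acid minus water).
AA_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_AVG <- 18.0153
WATER_MONO <- 18.010565

aa_vector <- function(protein) strsplit(toupper(protein), "")[[1]]

#' Scan for proprotein convertase consensus cleavage sites
#'
#' Matches the consensus (K/R)-(X)n-(K/R) with n in \{0, 2, 4, 6\} and X any
#' standard amino acid except cysteine. All matches for every n are reported,
#' overlaps included; the backbone is cut after the C-terminal basic residue of
#' the motif.
#'
#' @param protein Amino-acid string (one-letter codes).
#' @return A data.frame with columns `kind`, `start_aa`, `end_aa` (1-based
#'   inclusive), `spacer_n` and `cleave_after_aa`, sorted by position.
#' @export
scan_convertase_sites <- function(protein) {
  aa <- aa_vector(protein)
  L <- length(aa)
  basic <- aa %in% c("K", "R")
  res <- list()
  for (n in c(0L, 2L, 4L, 6L)) {
    p <- which(basic)
    p <- p[p + n + 1L <= L]
    if (!length(p)) next
    ok <- vapply(p, function(i) {
      if (!basic[i + n + 1L]) return(FALSE)
      if (n == 0L) return(TRUE)
      spacer <- aa[(i + 1L):(i + n)]
      !any(spacer == "C")
    }, NA)
    p <- p[ok]
    if (length(p)) {
      res[[length(res) + 1L]] <- data.frame(
        kind = "convertase_consensus", start_aa = p, end_aa = p + n + 1L,
        spacer_n = n, cleave_after_aa = p + n + 1L)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(kind = character(0), start_aa = integer(0),
                      end_aa = integer(0), spacer_n = integer(0),
                      cleave_after_aa = integer(0)))
  }
  out <- out[order(out$start_aa, out$spacer_n), ]
  rownames(out) <- NULL
  out
}

#' Detect literal furin RSRR cleavage sites
#'
#' @param protein Amino-acid string.
#' @return A data.frame in the same layout as [scan_convertase_sites()]
#'   (`kind = "furin_RXRR_literal"`), cleavage after the final R; overlapping
#'   occurrences are all reported.
#' @export
detect_furin_site <- function(protein) {
  m <- gregexpr("(?=RSRR)", toupper(protein), perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer(0) else as.integer(m)
  data.frame(kind = rep("furin_RXRR_literal", length(starts)),
             start_aa = starts, end_aa = starts + 3L,
             spacer_n = rep(2L, length(starts)),
             cleave_after_aa = starts + 3L)
}

#' Compute the molecular weight of a peptide
#'
#' Sum of residue masses plus one water, in kDa. Average masses by default
#' (matching gel-based size prediction); monoisotopic by flag. The empty
#' string is the boundary case (one water, 0.018 kDa).
#'
#' @param protein Amino-acid string over the 20 standard one-letter codes.
#' @param monoisotopic Use monoisotopic masses (default FALSE).
#' @return Molecular weight in kDa (numeric, unrounded).
#' @export
compute_mw <- function(protein, monoisotopic = FALSE) {
  masses <- if (monoisotopic) AA_MASS_MONO else AA_MASS_AVG
  water <- if (monoisotopic) WATER_MONO else WATER_AVG
  if (!nzchar(protein)) return(water / 1000)
  aa <- aa_vector(protein)
  m <- masses[aa]
  if (anyNA(m)) {
    stop("nonstandard residue(s): ",
         paste(unique(aa[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  (sum(m) + water) / 1000
}

#' Length of the maximal identical prefix of two proteins
#'
#' @param protein_a,protein_b Non-empty amino-acid strings.
#' @return Integer count of identical leading residues.
#' @export
shared_prefix <- function(protein_a, protein_b) {
  stopifnot(nzchar(protein_a), nzchar(protein_b))
  a <- aa_vector(protein_a); b <- aa_vector(protein_b)
  n <- min(length(a), length(b))
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(diff)) diff[1] - 1L else n
}

#' Annotate a precursor protein
#'
#' Computes cleavage sites, the precursor/propeptide/mature molecular weights
#' for a given processing scheme, the shared N-terminal identity with a
#' reference protein, and the cysteine census of the mature peptide.
#'
#' The default processing scheme follows the myostatin splice-variant
#' precursor: signal peptide aa 1–`signal_end`, propeptide from
#' `signal_end + 1` to `cleave_after_aa`, mature peptide from
#' `cleave_after_aa + 1` to the C-terminus. When `cleave_after_aa` is `NULL`
#' the most C-terminal convertase cleavage position inside the novel domain
#' (downstream of `novel_from_aa`) is used.
#'
#' @param protein Precursor amino-acid string.
#' @param signal_end Last residue of the (user-supplied) signal peptide
#'   (default 24).
#' @param cleave_after_aa Cleavage position, or `NULL` to pick it from the
#'   convertase scan.
#' @param novel_from_aa First residue of the novel domain used to restrict the
#'   automatic cleavage choice (default 1 = whole protein).
#' @param reference Optional reference protein for [shared_prefix()].
#' @param monoisotopic Passed to [compute_mw()].
#' @return A list of class `protein_annotation`.
#' @export
annotate_protein <- function(protein, signal_end = 24L,
                             cleave_after_aa = NULL, novel_from_aa = 1L,
                             reference = NULL, monoisotopic = FALSE) {
  sites <- scan_convertase_sites(protein)
  furin <- detect_furin_site(protein)
  L <- nchar(protein)
  if (is.null(cleave_after_aa)) {
    inside <- sites$cleave_after_aa[sites$start_aa >= novel_from_aa &
                                      sites$cleave_after_aa < L]
    if (!length(inside)) stop("no convertase site in the novel domain",
                              call. = FALSE)
    cleave_after_aa <- max(inside)
  }
  stopifnot(cleave_after_aa > signal_end, cleave_after_aa < L)
  mature <- substr(protein, cleave_after_aa + 1L, L)
  ann <- list(
    protein = protein,
    sites = rbind(sites, furin),
    signal_peptide = c(1L, as.integer(signal_end)),
    cleave_after_aa = as.integer(cleave_after_aa),
    precursor_mw = compute_mw(protein, monoisotopic),
    propeptide_mw = compute_mw(substr(protein, signal_end + 1L,
                                      cleave_after_aa), monoisotopic),
    mature_mw = compute_mw(mature, monoisotopic),
    mature_interval = c(cleave_after_aa + 1L, L),
    cysteine_count_mature = sum(aa_vector(mature) == "C"),
    identity_prefix_len = if (is.null(reference)) NA_integer_ else
      shared_prefix(protein, reference))
  class(ann) <- "protein_annotation"
  ann
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat(sprintf(paste0(
    "<protein_annotation> %d aa precursor: %.1f kDa; propeptide %.1f kDa; ",
    "mature (aa %d-%d) %.1f kDa, %d Cys\n"),
    nchar(x$protein), x$precursor_mw, x$propeptide_mw,
    x$mature_interval[1], x$mature_interval[2], x$mature_mw,
    x$cysteine_count_mature))
  invisible(x)
}
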