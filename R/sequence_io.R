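#' @keywords internal
#' @importFrom stats lm coef median optim rbinom rnorm runif setNames
#' @importFrom utils write.table read.delim head tail
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genomic sequence record
#'
#' A light container for a linear DNA sequence over \{A,C,G,T,N\}. Residues are
#' uppercased and RNA `U` is mapped to `T`. Circular topology is unsupported.
#'
#' @param id Accession or name.
#' @param residues DNA string.
#' @return An object of class `genomic_sequence` with fields `id`, `residues`
#'   and `length` (nt).
#' @export
genomic_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  if (!nzchar(residues)) {
    stop("sequence '", id, "': empty sequence", call. = FALSE)
  }
  bad <- unique(strsplit(gsub("[ACGTN]", "", residues), "")[[1]])
  if (length(bad)) {
    stop("sequence '", id, "': non-IUPAC character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "genomic_sequence")
}

#' @export
print.genomic_sequence <- function(x, ...) {
  cat(sprintf("<genomic_sequence> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

#' Read a (multi-)FASTA file
#'
#' Records are uppercased and `U` is mapped to `T`. Only \{A,C,G,T,N\} are
#' accepted; anything else is a format error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [genomic_sequence()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a FASTA file: ", path, " (",
                                           conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  recs <- lapply(seq_along(set), function(i) {
    genomic_sequence(ids[i], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write sequences as FASTA
#'
#' @param seqs A list of [genomic_sequence()] objects (or a single one).
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "genomic_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Construct a gene model
#'
#' Exon intervals are 1-based inclusive genomic coordinates, sorted 5'->3' in
#' transcription order on the gene's strand (i.e. descending genomic start for
#' minus-strand genes), non-overlapping. `cds_start` is the genomic position of
#' the first nucleotide of the start codon and must fall inside an exon.
#'
#' @param gene_id,sequence_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame with columns `start`, `end`.
#' @param cds_start Genomic position of the translation start.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, sequence_id, strand, exons, cds_start) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(exons$end < exons$start)) stop("exon end < start", call. = FALSE)
  ord <- order(exons$start)
  genomic_sorted <- exons[ord, , drop = FALSE]
  if (any(genomic_sorted$start[-1] <= genomic_sorted$end[-nrow(exons)])) {
    stop("exons overlap", call. = FALSE)
  }
  # store in transcription order
  exons <- if (strand == "+") genomic_sorted else
    genomic_sorted[rev(seq_len(nrow(genomic_sorted))), , drop = FALSE]
  rownames(exons) <- NULL
  cds_start <- as.integer(cds_start)
  if (!any(cds_start >= exons$start & cds_start <= exons$end)) {
    stop("cds_start ", cds_start, " does not fall inside an exon", call. = FALSE)
  }
  structure(list(gene_id = gene_id, sequence_id = sequence_id, strand = strand,
                 exons = exons, cds_start = cds_start),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d exon(s), cds_start %d\n",
              x$gene_id, x$sequence_id, x$strand, nrow(x$exons), x$cds_start))
  invisible(x)
}

#' Read a gene model from the JSON dialect
#'
#' Expected fields: `gene_id`, `sequence_id`, `strand`, `exons` (array of
#' `[start, end]` pairs or objects with `start`/`end`), `cds_start`.
#'
#' @param path Path to a JSON gene-model file.
#' @return A [gene_model()].
#' @export
read_gene_model_json <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- x$exons
  if (is.matrix(ex)) ex <- data.frame(start = ex[, 1], end = ex[, 2])
  gene_model(x$gene_id, x$sequence_id, x$strand, ex, x$cds_start)
}

#' Write a gene model to the JSON dialect
#' @param model A [gene_model()].
#' @param path Output path.
#' @export
write_gene_model_json <- function(model, path) {
  jsonlite::write_json(
    list(gene_id = model$gene_id, sequence_id = model$sequence_id,
         strand = model$strand,
         exons = model$exons, cds_start = model$cds_start),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses `exon` features grouped by `Parent` (or `ID` when no parent is given);
#' the CDS start is taken from the strand-appropriate extreme of the `CDS`
#' features of the same parent.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects.
#' @export
read_gene_model_gff3 <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent_of <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p)) as.character(p[1]) else as.character(gr$ID[i])
  }
  ex_idx <- which(type == "exon")
  if (!length(ex_idx)) stop("no exon features in ", path, call. = FALSE)
  parents <- vapply(ex_idx, parent_of, "")
  cds_idx <- which(type == "CDS")
  cds_parents <- vapply(cds_idx, parent_of, "")
  out <- lapply(unique(parents), function(p) {
    idx <- ex_idx[parents == p]
    strand <- as.character(BiocGenerics::strand(gr[idx[1]]))
    if (!strand %in% c("+", "-")) strand <- "+"
    exons <- data.frame(start = BiocGenerics::start(gr[idx]),
                        end = BiocGenerics::end(gr[idx]))
    cidx <- cds_idx[cds_parents == p]
    if (!length(cidx)) stop("no CDS feature for ", p, " in ", path, call. = FALSE)
    cds_start <- if (strand == "+") min(BiocGenerics::start(gr[cidx])) else
      max(BiocGenerics::end(gr[cidx]))
    gene_model(p, as.character(GenomicRanges::seqnames(gr[idx[1]])),
               strand, exons, cds_start)
  })
  names(out) <- unique(parents)
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the spliced mRNA of a gene model
#'
#' Concatenates the exon sequences in transcription order (minus-strand exons
#' are reverse-complemented) and records every exon/exon junction.
#'
#' @param seq A [genomic_sequence()].
#' @param model A [gene_model()] on that sequence.
#' @return An object of class `transcript` with fields `mrna`, `junctions`
#'   (0-based mRNA offsets of the first nucleotide after each junction),
#'   `segments` (map between genomic exon segments and mRNA coordinates),
#'   `source_model` and `spliced_introns`.
#' @export
extract_mrna <- function(seq, model) {
  stopifnot(inherits(seq, "genomic_sequence"), inherits(model, "gene_model"))
  ex <- model$exons
  if (any(ex$start < 1L) || any(ex$end > seq$length)) {
    stop("exon outside sequence ", seq$id, " (length ", seq$length, ")",
         call. = FALSE)
  }
  pieces <- substring(seq$residues, ex$start, ex$end)
  if (model$strand == "-") pieces <- vapply(pieces, revcomp, "")
  lens <- ex$end - ex$start + 1L
  m_end <- cumsum(lens)
  m_start <- m_end - lens + 1L
  segments <- data.frame(g_start = ex$start, g_end = ex$end,
                         m_start = m_start, m_end = m_end)
  junctions <- if (nrow(ex) > 1L) m_end[-nrow(ex)] else integer(0)
  spliced <- if (nrow(ex) > 1L) {
    gs <- if (model$strand == "+")
      data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    else data.frame(start = ex$end[-1] + 1L, end = ex$start[-nrow(ex)] - 1L)
    gs
  } else data.frame(start = integer(0), end = integer(0))
  structure(list(mrna = paste(pieces, collapse = ""),
                 junctions = as.integer(junctions),
                 segments = segments,
                 source_model = model,
                 spliced_introns = spliced),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s: %d nt, %d junction(s)\n",
              x$source_model$gene_id, nchar(x$mrna), length(x$junctions)))
  invisible(x)
}

#' Map a genomic position to a 1-based mRNA position
#'
#' @param transcript A [extract_mrna()] transcript.
#' @param pos Genomic position (1-based).
#' @return 1-based mRNA position; errors if `pos` is not exonic.
#' @export
genomic_to_mrna <- function(transcript, pos) {
  seg <- transcript$segments
  i <- which(pos >= seg$g_start & pos <= seg$g_end)
  if (!length(i)) stop("position ", pos, " is not exonic", call. = FALSE)
  i <- i[1]
  if (transcript$source_model$strand == "+") {
    seg$m_start[i] + (pos - seg$g_start[i])
  } else {
    seg$m_start[i] + (seg$g_end[i] - pos)
  }
}
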