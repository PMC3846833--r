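# End-to-end orchestration: scan -> characterize -> protein -> digest, with a
# validated config, per-stage logging and a MANIFEST so reruns are auditable
# and byte-reproducible.

#' Pipeline configuration
#'
#' @param profile A [splice_profile()].
#' @param start_policy `"annotated_atg"` or `"first_atg"`.
#' @param signal_peptide_end Last residue of the signal peptide (default 24).
#' @param monoisotopic Molecular-weight flag for [compute_mw()].
#' @param enzyme_table Restriction enzyme table (default [enzymes()]).
#' @param spr Named list of SPR fit options (`exclude_s`, `maxit`).
#' @param seed Integer seed for any stochastic stage.
#' @param ... Unknown keys are rejected.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(profile = splice_profile(),
                            start_policy = "annotated_atg",
                            signal_peptide_end = 24L,
                            monoisotopic = FALSE,
                            enzyme_table = enzymes(),
                            spr = list(exclude_s = 2, maxit = 2000L),
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(profile, "splice_profile"),
            start_policy %in% c("annotated_atg", "first_atg"))
  structure(list(profile = profile, start_policy = start_policy,
                 signal_peptide_end = as.integer(signal_peptide_end),
                 monoisotopic = isTRUE(monoisotopic),
                 enzyme_table = enzyme_table, spr = spr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline config from JSON
#'
#' Top-level keys mirror [pipeline_config()]; `profile` sub-keys mirror
#' [splice_profile()]. Unknown keys are rejected.
#' @param path JSON config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- if (!is.null(x$profile)) do.call(splice_profile, x$profile)
          else splice_profile()
  x$profile <- NULL
  args <- c(list(profile = prof), x)
  do.call(pipeline_config, args)
}

#' Run the discovery-to-report pipeline on one gene
#'
#' Stages: read inputs, scan for cryptic-intron candidates, splice the
#' top-ranked candidate, reconstruct the variant ORF and apply the NMD rule,
#' annotate the variant protein (cleavage sites, molecular weights, shared
#' N-terminal identity with the canonical protein), and predict restriction
#' fragments with probe hits. Reports are written under `out_dir` together
#' with a `MANIFEST.json` recording parameters and input checksums; reruns
#' with identical inputs/config/seed are byte-identical.
#'
#' @param genome_fasta Path to the genomic FASTA (first record used unless
#'   the gene model names another).
#' @param gene_model_file Gene model path (`.json` dialect or GFF3).
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param probe_interval Optional genomic interval for the Southern probe.
#' @return (Invisibly) a list with the candidate table, isoform record,
#'   protein annotation and digest report.
#' @export
run_pipeline <- function(genome_fasta, gene_model_file, out_dir,
                         config = pipeline_config(), probe_interval = NULL) {
  if (!file.exists(genome_fasta)) stop("genome FASTA not found: ", genome_fasta,
                                       call. = FALSE)
  if (!file.exists(gene_model_file)) stop("gene model not found: ",
                                          gene_model_file, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) message("[pipeline] ", sprintf(...))

  seqs <- read_fasta(genome_fasta)
  model <- if (grepl("\\.json$", gene_model_file, ignore.case = TRUE)) {
    read_gene_model_json(gene_model_file)
  } else {
    read_gene_model_gff3(gene_model_file)[[1]]
  }
  seq <- if (model$sequence_id %in% names(seqs)) seqs[[model$sequence_id]]
         else seqs[[1]]
  logf("loaded %s (%d nt), gene %s with %d exon(s)", seq$id, seq$length,
       model$gene_id, nrow(model$exons))

  logf("scan: profile ppt>=%.2f, branch window %d-%d, length %d-%d",
       config$profile$ppt_min_fraction, config$profile$branch_window[1],
       config$profile$branch_window[2], config$profile$min_intron_len,
       config$profile$max_intron_len)
  cands <- scan_cryptic_introns(seq, model, config$profile)
  write_candidates_tsv(cands, file.path(out_dir, "candidates.tsv"))
  write_candidates_bed(cands, seq$id, file.path(out_dir, "candidates.bed"))
  if (!nrow(cands)) stop("no cryptic-intron candidate found", call. = FALSE)

  canonical <- extract_mrna(seq, model)
  can_rec <- find_orf(canonical, config$start_policy)
  variant_tx <- splice_candidate(canonical, cands[1, ])
  rec <- find_orf(variant_tx, config$start_policy)
  logf("characterize: top candidate %d nt, variant ORF %d nt (%d aa), NMD %s",
       cands$length[1], rec$orf_length_nt, nchar(rec$protein), rec$nmd_flag)
  iso <- list(candidate = as.list(cands[1, ]),
              mrna_length = nchar(variant_tx$mrna),
              junctions = variant_tx$junctions,
              orf_start = rec$orf_start, orf_stop = rec$orf_stop,
              orf_length_nt = rec$orf_length_nt,
              protein = rec$protein, nmd_flag = rec$nmd_flag,
              ptc_distance = rec$ptc_distance,
              canonical_orf_length_nt = can_rec$orf_length_nt)
  jsonlite::write_json(iso, file.path(out_dir, "isoform.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fasta(list(genomic_sequence(paste0(model$gene_id, "_variant"),
                                    variant_tx$mrna)),
              file.path(out_dir, "variant_mrna.fasta"))

  ann <- annotate_protein(rec$protein,
                          signal_end = config$signal_peptide_end,
                          novel_from_aa = shared_prefix(rec$protein,
                                                        can_rec$protein) + 1L,
                          reference = can_rec$protein,
                          monoisotopic = config$monoisotopic)
  logf("protein: precursor %.1f kDa, propeptide %.1f kDa, mature %.1f kDa",
       ann$precursor_mw, ann$propeptide_mw, ann$mature_mw)
  jsonlite::write_json(unclass(ann), file.path(out_dir, "protein.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dig <- digest_report(seq, config$enzyme_table, probe_interval)
  write.table(dig, file.path(out_dir, "digest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logf("digest: %d fragment rows over %d enzyme(s)", nrow(dig),
       nrow(config$enzyme_table))

  manifest <- list(
    package = "crypticsplice",
    version = as.character(utils::packageVersion("crypticsplice")),
    inputs = list(genome_fasta = unname(tools::md5sum(genome_fasta)),
                  gene_model = unname(tools::md5sum(gene_model_file))),
    config = list(start_policy = config$start_policy,
                  signal_peptide_end = config$signal_peptide_end,
                  monoisotopic = config$monoisotopic,
                  profile = unclass(config$profile),
                  seed = config$seed),
    outputs = c("candidates.tsv", "candidates.bed", "isoform.json",
                "variant_mrna.fasta", "protein.json", "digest.tsv"),
    status = "ok")
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(candidates = cands, isoform = rec, protein = ann,
                 digest = dig))
}

# ---------------------------------------------------------------------------
# Command-line interface. Subcommands: scan, characterize (run's alias for the
# splice/ORF stages), protein, digest, conserve, spr-sim, spr-fit, simulate,
# run. Invoked from the installed script in exec/ or via cli_main().

#' Command-line entry point
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crypticsplice <subcommand> [options]",
    "subcommands: scan | run | simulate | spr-sim | spr-fit | conserve",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]; rest <- args[-1]
  status <- tryCatch({
    switch(sub,
      run = , scan = cli_run(rest, scan_only = identical(sub, "scan")),
      simulate = cli_simulate(rest),
      `spr-sim` = cli_spr_sim(rest),
      `spr-fit` = cli_spr_fit(rest),
      conserve = cli_conserve(rest),
      { message("unknown subcommand: ", sub, "\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(if (is.null(status)) 0L else status)
}

cli_run <- function(args, scan_only = FALSE) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--genome", type = "character"),
    optparse::make_option("--gene-model", type = "character", dest = "gene_model"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "out"),
    optparse::make_option("--seed", type = "integer", default = 1L)))
  o <- optparse::parse_args(parser, args = args)
  cfg <- if (!is.null(o$config)) read_pipeline_config(o$config)
         else pipeline_config(seed = o$seed)
  if (scan_only) {
    seqs <- read_fasta(o$genome)
    model <- if (grepl("\\.json$", o$gene_model)) read_gene_model_json(o$gene_model)
             else read_gene_model_gff3(o$gene_model)[[1]]
    cands <- scan_cryptic_introns(seqs[[1]], model, cfg$profile)
    dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
    write_candidates_tsv(cands, file.path(o$out, "candidates.tsv"))
    write_candidates_bed(cands, seqs[[1]]$id, file.path(o$out, "candidates.bed"))
  } else {
    run_pipeline(o$genome, o$gene_model, o$out, cfg)
  }
  0L
}

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--out", type = "character", default = "sim"),
    optparse::make_option("--seed", type = "integer", default = 1L)))
  o <- optparse::parse_args(parser, args = args)
  g <- make_gene(seed = o$seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write_fasta(list(g$sequence), file.path(o$out, "gene.fasta"))
  write_gene_model_json(g$model, file.path(o$out, "gene_model.json"))
  jsonlite::write_json(g$truth, file.path(o$out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  0L
}

cli_spr_sim <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--ka", type = "double", default = 4.41e4),
    optparse::make_option("--kd", type = "double", default = 4.32e-6),
    optparse::make_option("--rmax", type = "double", default = 100),
    optparse::make_option("--noise", type = "double", default = 1),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "sensorgrams.csv")))
  o <- optparse::parse_args(parser, args = args)
  conc <- c(6.25, 12.5, 25, 50, 100) * 1e-9
  sgs <- lapply(seq_along(conc), function(i)
    simulate_sensorgram(o$ka, o$kd, o$rmax, conc[i], noise_sd = o$noise,
                        seed = o$seed + i))
  write_sensorgrams_csv(sgs, o$out)
  0L
}

cli_spr_fit <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--out", type = "character", default = "fit.json")))
  o <- optparse::parse_args(parser, args = args)
  fit <- fit_kinetics(read_sensorgrams_csv(o$input))
  jsonlite::write_json(unclass(fit), o$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  0L
}

cli_conserve <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--fasta", type = "character"),
    optparse::make_option("--table", type = "character"),
    optparse::make_option("--out", type = "character", default = "calls.tsv")))
  o <- optparse::parse_args(parser, args = args)
  seqs <- read_fasta(o$fasta)
  tab <- read.delim(o$table, stringsAsFactors = FALSE)
  calls <- classify_set(seqs, tab)
  write.table(calls, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
  0L
}
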