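# End-to-end pipeline orchestration.
#
# One run reads all inputs up front (any unreadable input aborts before a
# single file is written), assigns toxin groups at the lenient cutoff, and
# materializes one directory per group holding exactly eleven files:
#
#   01_candidates_nt.fasta   nucleotide ORF sequences (full and partial)
#   02_query_proteins.fasta  the group's query proteins
#   03_query_taxonomy.tsv    organism/lineage of the queries
#   04_query_records.txt     simplified keyed dump of the query metadata
#   05_candidates_aa.fasta   translated proteins, complete ORFs only
#   06_combined_unaligned.fasta  queries + candidate proteins
#   07_combined_aligned.fasta    the same, aligned
#   08_signal.tsv            signal-peptide predictions
#   09_mature_peptides.fasta mature peptides where a signal is present
#   10_tree.nwk              neighbor-joining gene tree
#   11_expression.tsv        per-member expression across samples
#
# plus top-level TPM.fasta, screening_verdicts.tsv, stringency_sweep.tsv,
# tissue_report.tsv and run_manifest.json. The run is fully deterministic
# for a given config, so re-runs are byte-identical.

GROUP_FILES <- c("01_candidates_nt.fasta", "02_query_proteins.fasta",
                 "03_query_taxonomy.tsv", "04_query_records.txt",
                 "05_candidates_aa.fasta", "06_combined_unaligned.fasta",
                 "07_combined_aligned.fasta", "08_signal.tsv",
                 "09_mature_peptides.fasta", "10_tree.nwk",
                 "11_expression.tsv")

#' Build and validate a pipeline configuration
#'
#' @param transcriptome Path to the assembled transcriptome FASTA.
#' @param expression Character vector of expression-table paths; names are
#'   the sample labels (unnamed entries use the file base name).
#' @param hits Path to the 12-column toxin homology-search table.
#' @param meta Path to the toxin-query metadata table.
#' @param queries Optional path to the query protein FASTA (needed for the
#'   combined alignments and trees; without it those files hold candidates
#'   only).
#' @param nontoxin_hits Optional path to a 12-column non-toxin hit table
#'   for the reciprocal screen.
#' @param signal Optional path to external signal predictions; rows there
#'   override the built-in rule-based predictor.
#' @param outdir Output directory (must not exist or be empty).
#' @param evalue_cutoff Lenient grouping cutoff (default 1e-6).
#' @param stringent_cutoff Stringent cutoff reported in the sweep table
#'   (default 1e-20).
#' @param min_orf_aa Minimum ORF length in residues (default 50; toxin
#'   precursors are short, so this is deliberately permissive).
#' @param tpm_cutoff TPM filter threshold, strict (default 1.0).
#' @param highlight_tpm Tissue-report highlight threshold (default 100).
#' @param margin_orders Screening margin in orders of magnitude (default 0).
#' @param multi_group Transcripts may join every group they hit (default).
#' @param seed Integer recorded in the manifest (the run itself draws no
#'   random numbers).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(transcriptome, expression, hits, meta,
                            queries = NULL, nontoxin_hits = NULL,
                            signal = NULL, outdir,
                            evalue_cutoff = 1e-6, stringent_cutoff = 1e-20,
                            min_orf_aa = 50L, tpm_cutoff = 1.0,
                            highlight_tpm = 100, margin_orders = 0,
                            multi_group = TRUE, seed = 1L) {
  stopifnot(evalue_cutoff > 0, stringent_cutoff > 0, min_orf_aa >= 1L,
            tpm_cutoff >= 0, margin_orders >= 0)
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    names(expression) <- tools::file_path_sans_ext(basename(expression))
  }
  structure(list(transcriptome = transcriptome, expression = expression,
                 hits = hits, meta = meta, queries = queries,
                 nontoxin_hits = nontoxin_hits, signal = signal,
                 outdir = outdir, evalue_cutoff = evalue_cutoff,
                 stringent_cutoff = stringent_cutoff,
                 min_orf_aa = as.integer(min_orf_aa),
                 tpm_cutoff = tpm_cutoff, highlight_tpm = highlight_tpm,
                 margin_orders = margin_orders, multi_group = multi_group,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full triage pipeline
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a run summary: group/transcript/candidate counts, the
#'   per-group table, the screening verdicts and the stringency sweep.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[toxtriage] ", ...)

  # ---- read every input before writing anything -------------------------
  transcripts <- read_transcriptome(config$transcriptome)
  expr <- do.call(rbind, lapply(names(config$expression), function(s) {
    parse_expression_table(config$expression[[s]], sample_label = s)
  }))
  hits <- parse_blast_tab(config$hits)
  meta <- read_query_meta(config$meta)
  queries <- if (!is.null(config$queries)) read_fasta(config$queries) else
    data.frame(id = character(), desc = character(), seq = character(),
               stringsAsFactors = FALSE)
  nthits <- if (!is.null(config$nontoxin_hits))
    parse_blast_tab(config$nontoxin_hits) else NULL
  ext_signal <- if (!is.null(config$signal))
    parse_signal_table(config$signal) else NULL
  missing_tx <- setdiff(hits$subject_id, transcripts$id)
  if (length(missing_tx) > 0L) {
    stop("hit table references transcript(s) absent from the transcriptome: ",
         paste(utils::head(lex_sort(missing_tx), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (dir.exists(config$outdir) &&
      length(list.files(config$outdir, all.files = TRUE, no.. = TRUE)) > 0L) {
    stop("output directory is not empty: ", config$outdir, call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say("inputs: ", nrow(transcripts), " transcripts, ", nrow(hits),
      " toxin hits, ", nrow(meta), " queries, ",
      length(unique(expr$sample)), " sample(s)")

  # ---- grouping and stringency sweep ------------------------------------
  groups <- assign_groups(hits, meta, config$evalue_cutoff,
                          config$multi_group)
  sweep <- stringency_sweep(hits, meta,
                            c(config$stringent_cutoff, config$evalue_cutoff))
  member_ids <- unique(as.character(unlist(lapply(groups, function(g)
    g$members$transcript_id))))
  member_ids <- lex_sort(member_ids)
  say(length(groups), " toxin group(s), ", length(member_ids),
      " member transcript(s)")

  # ---- ORFs and screening for member transcripts ------------------------
  seq_of <- stats::setNames(transcripts$seq, transcripts$id)
  best <- lapply(member_ids, function(id)
    best_orf(seq_of[[id]], config$min_orf_aa, id))
  names(best) <- member_ids
  no_orf <- member_ids[vapply(best, is.null, logical(1))]
  if (length(no_orf) > 0L) {
    say(length(no_orf), " member transcript(s) had no ORF of >= ",
        config$min_orf_aa, " aa and were not screened")
  }
  screened <- setdiff(member_ids, no_orf)
  verdicts <- do.call(rbind, lapply(screened, function(id) {
    classify_candidate(id,
                       hits[hits$subject_id == id, , drop = FALSE],
                       if (is.null(nthits)) NULL else
                         nthits[nthits$subject_id == id, , drop = FALSE],
                       config$margin_orders)
  }))
  if (is.null(verdicts)) {
    verdicts <- classify_candidate("none", hits[0, ], NULL)[0, ]
  }
  candidates <- verdicts$protein_id[verdicts$verdict == "candidate"]
  say(length(candidates), " candidate(s) after reciprocal screening")

  # ---- top-level products ----------------------------------------------
  tpm_pass <- tpm_filter(transcripts, expr, config$tpm_cutoff)
  write_fasta(tpm_pass, file.path(config$outdir, "TPM.fasta"))
  write_tsv(verdicts, file.path(config$outdir, "screening_verdicts.tsv"))
  write_tsv(sweep, file.path(config$outdir, "stringency_sweep.tsv"))
  write_tsv(tissue_report(candidates, expr, config$highlight_tpm),
            file.path(config$outdir, "tissue_report.tsv"))

  # ---- per-group directories -------------------------------------------
  for (g in groups) {
    write_group_dir(g, config, transcripts, best, expr, meta, queries,
                    ext_signal)
  }

  # ---- manifest ---------------------------------------------------------
  input_paths <- c(transcriptome = config$transcriptome,
                   hits = config$hits, meta = config$meta,
                   queries = config$queries,
                   nontoxin_hits = config$nontoxin_hits,
                   signal = config$signal, unlist(config$expression))
  manifest <- list(
    package = "toxtriage",
    version = as.character(utils::packageVersion("toxtriage")),
    seed = config$seed,
    thresholds = config[c("evalue_cutoff", "stringent_cutoff", "min_orf_aa",
                          "tpm_cutoff", "highlight_tpm", "margin_orders",
                          "multi_group")],
    inputs = as.list(tools::md5sum(unname(input_paths))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             con <- file(file.path(config$outdir, "run_manifest.json"), "wb"))
  close(con)

  group_table <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$name, display_name = g$display_name,
               n_queries = length(g$queries), n_members = nrow(g$members),
               stringsAsFactors = FALSE)
  }))
  invisible(list(n_groups = length(groups),
                 n_transcripts = length(member_ids),
                 n_candidates = length(candidates),
                 n_tpm_pass = nrow(tpm_pass),
                 groups = group_table, verdicts = verdicts, sweep = sweep,
                 candidates = lex_sort(candidates)))
}

# Materialize the 11 fixed files of one toxin-group directory.
write_group_dir <- function(g, config, transcripts, best, expr, meta,
                            queries, ext_signal) {
  dir <- file.path(config$outdir, g$name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seq_of <- stats::setNames(transcripts$seq, transcripts$id)
  members <- g$members$transcript_id
  orfs <- best[members]
  orfs <- orfs[!vapply(orfs, is.null, logical(1))]

  # (1) nucleotide ORFs, full and partial
  nt_recs <- do.call(rbind, lapply(orfs, function(o) {
    sub <- substr(seq_of[[o$transcript_id]], o$start, o$end)
    if (o$strand == "-") sub <- revcomp(sub)
    data.frame(id = o$transcript_id,
               desc = sprintf("%s strand=%s frame=%d %d-%d", o$completeness,
                              o$strand, o$frame, o$start, o$end),
               seq = sub, stringsAsFactors = FALSE)
  }))
  if (is.null(nt_recs)) nt_recs <- transcripts[0, ]
  write_fasta(nt_recs, file.path(dir, "01_candidates_nt.fasta"))

  # (2) query proteins, (3) taxonomy, (4) keyed metadata dump
  qrecs <- queries[queries$id %in% g$queries, , drop = FALSE]
  write_fasta(qrecs, file.path(dir, "02_query_proteins.fasta"))
  gmeta <- meta[meta$accession %in% g$queries, , drop = FALSE]
  gmeta <- gmeta[lex_order(gmeta$accession), , drop = FALSE]
  write_tsv(gmeta, file.path(dir, "03_query_taxonomy.tsv"))
  dump <- unlist(lapply(seq_len(nrow(gmeta)), function(i) c(
    paste0("ACCESSION   ", gmeta$accession[i]),
    paste0("DEFINITION  ", gmeta$protein_name[i]),
    paste0("ORGANISM    ", gmeta$organism[i]),
    paste0("LINEAGE     ", gmeta$lineage[i]),
    "//")))
  con <- file(file.path(dir, "04_query_records.txt"), "wb")
  writeLines(if (is.null(dump)) character() else dump, con, sep = "\n")
  close(con)

  # (5) proteins from complete ORFs only
  complete <- Filter(function(o) o$completeness == "complete", orfs)
  aa_recs <- do.call(rbind, lapply(complete, function(o) {
    data.frame(id = o$transcript_id, desc = "complete", seq = o$protein,
               stringsAsFactors = FALSE)
  }))
  if (is.null(aa_recs)) aa_recs <- transcripts[0, ]
  write_fasta(aa_recs, file.path(dir, "05_candidates_aa.fasta"))

  # (6,7) combined query + candidate proteins, unaligned and aligned
  cand_prot <- vapply(orfs, `[[`, character(1), "protein")
  names(cand_prot) <- vapply(orfs, `[[`, character(1), "transcript_id")
  combined <- c(stats::setNames(qrecs$seq, qrecs$id), cand_prot)
  comb_recs <- data.frame(id = names(combined), desc = "", seq = unname(combined),
                          stringsAsFactors = FALSE)
  write_fasta(comb_recs, file.path(dir, "06_combined_unaligned.fasta"))
  aln <- if (length(combined) >= 2L) progressive_msa(combined) else combined
  write_fasta(data.frame(id = names(aln), desc = "", seq = unname(aln),
                         stringsAsFactors = FALSE),
              file.path(dir, "07_combined_aligned.fasta"))

  # (8,9) signal predictions and mature peptides
  sig <- if (length(cand_prot) > 0L) {
    predict_signals(cand_prot, ext_signal)
  } else {
    data.frame(protein_id = character(), has_signal = logical(),
               cleavage_after = integer(), score = numeric(),
               source = character(), stringsAsFactors = FALSE)
  }
  write_tsv(sig, file.path(dir, "08_signal.tsv"))
  mature <- do.call(rbind, lapply(which(sig$has_signal), function(i) {
    sp <- split_precursor(cand_prot[[sig$protein_id[i]]], sig[i, ])
    data.frame(id = sp$protein_id, desc = "mature", seq = sp$mature,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mature)) mature <- transcripts[0, ]
  write_fasta(mature, file.path(dir, "09_mature_peptides.fasta"))

  # (10) neighbor-joining gene tree on the combined alignment
  tree_path <- file.path(dir, "10_tree.nwk")
  if (length(aln) >= 3L) {
    write_newick(neighbor_joining(p_distance(aln)), tree_path)
  } else if (length(aln) == 2L) {
    d <- p_distance(aln)
    write_newick(two_leaf_tree(names(aln), d[1L, 2L]), tree_path)
  } else {
    con <- file(tree_path, "wb")
    writeLines(paste0(names(aln), ";"), con, sep = "\n")
    close(con)
  }

  # (11) expression report
  write_tsv(group_expression_table(g, expr),
            file.path(dir, "11_expression.tsv"))
  invisible(dir)
}
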