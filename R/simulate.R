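# Deterministic synthetic-data generator.
#
# Emulates the shape of a venom-gland transcriptome study: a handful of
# cysteine-rich secreted toxin families (short precursors with a signal
# peptide and a disulfide-bonded mature core), embedded among housekeeping
# decoy transcripts, plus the homology-search table, query metadata,
# per-tissue expression, and a ground-truth table tying everything
# together. The generator writes the hit table directly instead of running
# a real homology search, because the pipeline's contract starts at the
# tabular search output.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
AA_NO_C <- setdiff(AA20, "C")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons per amino acid, from the standard genetic code.
CODONS_BY_AA <- split(names(GENETIC_CODE_1), unname(GENETIC_CODE_1))

FAMILY_NAME_POOL <- c(
  "Alpha-conotoxin S1", "Kunitz-type serine protease inhibitor 1",
  "Phospholipase A2 V-1", "Snake venom metalloproteinase E2",
  "Venom allergen 3", "Cysteine-rich venom protein V5",
  "Neprilysin-1", "Delta-latroinsectotoxin-Lt1a")

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# A signal peptide that the rule-based predictor provably cleaves after
# exactly `k` residues: M, a basic residue, a hydrophobic-but-not-small
# core (L/I/F/V keeps every earlier window from qualifying), and an
# A-x-A-like c-region at k-2..k.
make_signal <- function(k) {
  stopifnot(k >= 12L, k <= 35L)
  aa <- c("M", sample(c("K", "R"), 1L),
          sample(c("L", "I", "F", "V"), k - 5L, replace = TRUE),
          "A", "L", "A")
  paste(aa, collapse = "")
}

#' Simulate one toxin gene family
#'
#' Builds a random mature core (40-80 residues, at least six cysteines at
#' family-fixed positions) and derives members by point substitutions at
#' non-cysteine sites, so the cysteine skeleton is shared by the whole
#' family. Every member carries the family signal peptide.
#'
#' @param name Family (protein) name.
#' @param n_members Number of member precursors (>= 1).
#' @param seed Integer seed; identical calls give identical output.
#' @param sub_rate Per-site substitution rate at non-cysteine sites; drawn
#'   from \[0.05, 0.2\] when `NULL`.
#' @return List with `name`, `consensus` (signal + core), `members` (named
#'   character vector of precursors), `signal_len`, `sub_rate`.
#' @export
simulate_family <- function(name, n_members, seed, sub_rate = NULL) {
  stopifnot(n_members >= 1L)
  with_seed(seed, {
    core_len <- sample(40:80, 1L)
    n_cys <- sample(6:8, 1L)
    cys_pos <- sort(sample(seq_len(core_len), n_cys))
    core <- sample(AA_NO_C, core_len, replace = TRUE)
    core[cys_pos] <- "C"
    if (is.null(sub_rate)) sub_rate <- stats::runif(1L, 0.05, 0.2)
    signal <- make_signal(sample(15:25, 1L))
    members <- vapply(seq_len(n_members), function(i) {
      m <- core
      free <- setdiff(seq_len(core_len), cys_pos)
      mut <- free[stats::runif(length(free)) < sub_rate]
      m[mut] <- vapply(m[mut], function(old)
        sample(setdiff(AA_NO_C, old), 1L), character(1))
      paste0(signal, paste(m, collapse = ""))
    }, character(1))
    names(members) <- sprintf("%s_m%d", normalize_group_name(name),
                              seq_len(n_members))
    list(name = name, consensus = paste0(signal, paste(core, collapse = "")),
         members = members, signal_len = nchar(signal), sub_rate = sub_rate)
  })
}

# Reverse-translate a protein with uniformly random synonymous codons.
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(x) {
    cods <- CODONS_BY_AA[[x]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# Embed a coding sequence in UTRs. An in-frame stop ends the 5' UTR so the
# planted ORF is stop-bounded upstream and reported as complete with these
# exact coordinates.
plant_orf <- function(protein) {
  cds <- paste0(reverse_translate(protein),
                sample(STOP_CODONS, 1L))
  u5 <- sample(7:20, 1L) * 3L
  utr5 <- paste0(rand_nt(u5 - 3L), sample(STOP_CODONS, 1L))
  utr3 <- rand_nt(sample(20:60, 1L))
  list(seq = paste0(utr5, cds, utr3),
       start = u5 + 1L, end = u5 + nchar(cds))
}

#' Simulate every pipeline input with planted ground truth
#'
#' Writes, under `outdir`: `transcriptome.fasta`, `queries.fasta`,
#' `query_meta.tsv`, `toxin_hits.tsv`, `nontoxin_hits.tsv`, one
#' `expression_<tissue>.tsv` per tissue, and `truth.tsv`. Toxin transcripts
#' are family members with a planted ORF (a random half reverse-
#' complemented) and hits only to their own family query; decoys carry no
#' toxin hits, only non-toxin hits. Venom-gland TPM is high (50-500) for
#' toxins and low (0-20) for decoys and other tissues.
#'
#' @param n_families,members_per_family,n_decoys Counts (>= 1).
#' @param tissues Tissue labels; the first is treated as the venom gland.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param outdir Output directory; must not already contain files.
#' @return Invisibly, a list with `truth` (the ground-truth data frame) and
#'   `paths` (named list of all written files).
#' @export
simulate_inputs <- function(n_families = 5L, members_per_family = 4L,
                            n_decoys = 150L,
                            tissues = c("venom_gland", "carcass"),
                            seed = 1L, outdir) {
  stopifnot(n_families >= 1L, members_per_family >= 1L, n_decoys >= 1L,
            length(tissues) >= 1L)
  if (dir.exists(outdir) && length(list.files(outdir, all.files = TRUE,
                                              no.. = TRUE)) > 0L) {
    stop("output directory is not empty: ", outdir, call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fam_names <- if (n_families <= length(FAMILY_NAME_POOL)) {
    FAMILY_NAME_POOL[seq_len(n_families)]
  } else {
    c(FAMILY_NAME_POOL,
      sprintf("Synthetic toxin family %d",
              seq_len(n_families - length(FAMILY_NAME_POOL))))
  }
  families <- lapply(seq_len(n_families), function(i) {
    simulate_family(fam_names[i], members_per_family, child_seed(seed, i))
  })

  with_seed(child_seed(seed, 0L), {
    tx_rows <- list()
    truth_rows <- list()
    hit_rows <- list()
    nt_rows <- list()
    accs <- sprintf("TXQ%03d", seq_len(n_families))

    for (i in seq_len(n_families)) {
      fam <- families[[i]]
      for (j in seq_along(fam$members)) {
        prot <- fam$members[[j]]
        planted <- plant_orf(prot)
        strand <- sample(c("+", "-"), 1L)
        seq <- planted$seq
        s <- planted$start; e <- planted$end
        if (strand == "-") {
          L <- nchar(seq)
          seq <- revcomp(seq)
          tmp <- s
          s <- L - e + 1L
          e <- L - tmp + 1L
        }
        id <- names(fam$members)[j]
        evalue <- 10^stats::runif(1L, -50, -10)
        plen <- nchar(prot)
        # coding span excludes the stop codon; on the minus strand the stop
        # sits at the low-coordinate end
        cod <- if (strand == "+") c(s, e - 3L) else c(s + 3L, e)
        sc <- if (strand == "+") cod else rev(cod)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = accs[i], subject_id = id,
          pct_identity = round((1 - fam$sub_rate) * 100, 1),
          aln_len = plen,
          mismatches = round(fam$sub_rate * plen),
          gap_opens = 0, q_start = 1, q_end = plen,
          s_start = sc[1L], s_end = sc[2L],
          evalue = evalue,
          bit_score = round(60 - 2 * log10(evalue), 1),
          stringsAsFactors = FALSE)
        # a weak non-toxin hit, 5-15 orders worse, to exercise the rule
        nt_rows[[length(nt_rows) + 1L]] <- data.frame(
          query_id = sprintf("NTX%03d", sample.int(50L, 1L)),
          subject_id = id, pct_identity = round(stats::runif(1L, 25, 40), 1),
          aln_len = plen, mismatches = round(0.6 * plen), gap_opens = 1,
          q_start = 1, q_end = plen, s_start = cod[1L], s_end = cod[2L],
          evalue = min(evalue * 10^stats::runif(1L, 5, 15), 1),
          bit_score = round(stats::runif(1L, 20, 40), 1),
          stringsAsFactors = FALSE)
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          id = id, desc = "", seq = seq, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          transcript_id = id, class = "toxin", family = fam$name,
          orf_start = s, orf_end = e, strand = strand,
          signal_len = fam$signal_len,
          group_key = normalize_group_name(fam$name),
          verdict = "candidate", stringsAsFactors = FALSE)
      }
    }

    for (k in seq_len(n_decoys)) {
      id <- sprintf("DEC%04d", k)
      prot <- paste(c("M", sample(AA20, sample(30:120, 1L),
                                  replace = TRUE)), collapse = "")
      planted <- plant_orf(prot)
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        id = id, desc = "", seq = planted$seq, stringsAsFactors = FALSE)
      plen <- nchar(prot)
      nt_rows[[length(nt_rows) + 1L]] <- data.frame(
        query_id = sprintf("NTX%03d", sample.int(50L, 1L)),
        subject_id = id, pct_identity = round(stats::runif(1L, 30, 90), 1),
        aln_len = plen, mismatches = round(0.3 * plen), gap_opens = 0,
        q_start = 1, q_end = plen,
        s_start = planted$start, s_end = planted$end - 3L,
        evalue = 10^stats::runif(1L, -40, -5),
        bit_score = round(stats::runif(1L, 30, 80), 1),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = id, class = "decoy", family = NA_character_,
        orf_start = planted$start, orf_end = planted$end, strand = "+",
        signal_len = NA_integer_, group_key = NA_character_,
        verdict = "unevaluated", stringsAsFactors = FALSE)
    }

    transcriptome <- do.call(rbind, tx_rows)
    truth <- do.call(rbind, truth_rows)
    hits <- do.call(rbind, hit_rows)
    nthits <- do.call(rbind, nt_rows)

    # per-tissue expression; tissues[1] is the venom gland
    expr_paths <- list()
    for (t in seq_along(tissues)) {
      is_tox <- truth$class == "toxin"
      tpm <- ifelse(is_tox & t == 1L,
                    stats::runif(nrow(truth), 50, 500),
                    stats::runif(nrow(truth), 0, 20))
      tpm <- round(tpm, 2)
      truth[[paste0("tpm_", tissues[t])]] <- tpm
      tab <- data.frame(
        transcript_id = truth$transcript_id,
        length = nchar(transcriptome$seq),
        expected_count = round(tpm * stats::runif(nrow(truth), 5, 20), 1),
        TPM = tpm,
        FPKM = round(tpm * stats::runif(nrow(truth), 0.8, 1.2), 2),
        stringsAsFactors = FALSE)
      p <- file.path(outdir, sprintf("expression_%s.tsv", tissues[t]))
      write_tsv(tab, p)
      expr_paths[[tissues[t]]] <- p
    }

    meta <- data.frame(
      accession = accs,
      protein_name = fam_names,
      organism = sprintf("Synthetica venomosa %d", seq_len(n_families)),
      lineage = "Eukaryota;Metazoa;Synthetica",
      stringsAsFactors = FALSE)
    queries <- data.frame(
      id = accs, desc = fam_names,
      seq = vapply(families, `[[`, character(1), "consensus"),
      stringsAsFactors = FALSE)

    paths <- list(
      transcriptome = file.path(outdir, "transcriptome.fasta"),
      queries = file.path(outdir, "queries.fasta"),
      query_meta = file.path(outdir, "query_meta.tsv"),
      toxin_hits = file.path(outdir, "toxin_hits.tsv"),
      nontoxin_hits = file.path(outdir, "nontoxin_hits.tsv"),
      expression = expr_paths,
      truth = file.path(outdir, "truth.tsv"))
    write_fasta(transcriptome, paths$transcriptome)
    write_fasta(queries, paths$queries)
    write_tsv(meta, paths$query_meta)
    write_blast_tab(hits, paths$toxin_hits)
    write_blast_tab(nthits, paths$nontoxin_hits)
    write_tsv(truth, paths$truth)
    invisible(list(truth = truth, paths = paths))
  })
}

# Deterministic TSV writer (LF line endings, no quoting, NA as "NA").
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) {
        ifelse(is.na(col), "NA", sprintf("%.15g", col))
      } else {
        ifelse(is.na(col), "NA", as.character(col))
      }
    }, character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
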