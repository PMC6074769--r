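# Tabular input formats: 12-column homology search output (outfmt 6),
# expression quantifier tables, signal-prediction short format, and the
# toxin-query metadata table.

BLAST6_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")
BLAST6_NUMERIC <- BLAST6_COLS[3:12]

#' Parse 12-column tabular homology-search output (outfmt 6)
#'
#' Queries are toxin proteins, subjects are transcripts. Coordinates are
#' 1-based inclusive; a hit with `s_start > s_end` lies on the minus strand
#' of the transcript (the de-facto tabular convention), exposed in the
#' derived `strand` column.
#'
#' @param path Path to a headerless tab-delimited file with the default
#'   12-column layout (query, subject, identity, alignment length,
#'   mismatches, gap opens, q. start/end, s. start/end, E-value, bit score).
#' @return Data frame of hits, one row per line, with a derived `strand`
#'   column (`"+"`/`"-"`). Empty input gives zero rows.
#' @export
parse_blast_tab <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)),
      BLAST6_COLS), stringsAsFactors = FALSE)
    out$strand <- character()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-delimited fields, found %d",
                 i, nf[i]), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- is.na(v) & !is.na(m[, j])
    if (any(bad)) {
      stop(sprintf("line %d, column %d: cannot parse number '%s'",
                   which(bad)[1L], j, m[which(bad)[1L], j]), call. = FALSE)
    }
    hits[[BLAST6_COLS[j]]] <- v
  }
  if (any(hits$evalue < 0)) {
    stop("line ", which(hits$evalue < 0)[1L], ": negative E-value",
         call. = FALSE)
  }
  coords <- c("q_start", "q_end", "s_start", "s_end")
  for (cc in coords) {
    if (any(hits[[cc]] < 1)) {
      stop("line ", which(hits[[cc]] < 1)[1L], ": coordinate ", cc, " < 1",
           call. = FALSE)
    }
  }
  if (any(hits$q_start > hits$q_end)) {
    stop("line ", which(hits$q_start > hits$q_end)[1L],
         ": q_start > q_end", call. = FALSE)
  }
  hits$strand <- ifelse(hits$s_start > hits$s_end, "-", "+")
  hits
}

#' Serialize hits back to the 12-column tabular format
#'
#' Inverse of [parse_blast_tab()]: numbers are written with enough digits
#' that a parse of the output reproduces the input exactly.
#'
#' @param hits Data frame as returned by [parse_blast_tab()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_blast_tab <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0L) {
    num <- vapply(BLAST6_NUMERIC, function(cc) {
      sprintf("%.15g", hits[[cc]])
    }, character(nrow(hits)))
    num <- matrix(num, nrow = nrow(hits))
    writeLines(paste(hits$query_id, hits$subject_id,
                     apply(num, 1L, paste, collapse = "\t"), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Parse a per-transcript expression table
#'
#' Reads one tab-delimited table with a header row, in the dialect common to
#' transcript quantifiers (transcript id in the first column; TPM and
#' optionally FPKM and expected-count columns found by header name).
#'
#' @param path Path to the table.
#' @param sample_label Label attached to every record (tissue or sample).
#' @param id_col Header name of the transcript id column; default the first
#'   column.
#' @param tpm_col,fpkm_col,count_col Candidate header names searched in
#'   order; the first match wins. A missing TPM column is an error.
#' @return Data frame with columns `transcript_id`, `sample`, `tpm`, `fpkm`,
#'   `expected_count` (the last two `NA` when absent).
#' @export
parse_expression_table <- function(path, sample_label,
                                   id_col = NULL,
                                   tpm_col = c("TPM", "tpm"),
                                   fpkm_col = c("FPKM", "fpkm"),
                                   count_col = c("expected_count", "est_counts",
                                                 "NumReads")) {
  stopifnot(is.character(sample_label), length(sample_label) == 1L)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(tab)
  if (is.null(id_col)) id_col <- hdr[1L]
  if (!id_col %in% hdr) {
    stop("id column '", id_col, "' not found; available headers: ",
         paste(hdr, collapse = ", "), call. = FALSE)
  }
  pick <- function(cands) {
    hit <- cands[cands %in% hdr]
    if (length(hit) == 0L) NA_character_ else hit[1L]
  }
  tpm_use <- pick(tpm_col)
  if (is.na(tpm_use)) {
    stop("no TPM column found (tried: ", paste(tpm_col, collapse = ", "),
         "); available headers: ", paste(hdr, collapse = ", "),
         call. = FALSE)
  }
  tpm <- as.numeric(tab[[tpm_use]])
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    stop("TPM values must be finite and >= 0 (row ",
         which(!is.finite(tpm) | tpm < 0)[1L], ")", call. = FALSE)
  }
  grab <- function(cands) {
    cc <- pick(cands)
    if (is.na(cc)) rep(NA_real_, nrow(tab)) else as.numeric(tab[[cc]])
  }
  out <- data.frame(transcript_id = as.character(tab[[id_col]]),
                    sample = sample_label, tpm = tpm,
                    fpkm = grab(fpkm_col), expected_count = grab(count_col),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$transcript_id)) {
    stop("duplicate transcript id in expression table: ",
         out$transcript_id[duplicated(out$transcript_id)][1L], call. = FALSE)
  }
  out
}

#' Parse short-format signal-peptide predictions
#'
#' Tab-delimited rows: protein id, Y/N flag, cleavage position (`-` when
#' absent), score. Lines starting with `#` are comments. "Cleavage after k"
#' means the signal is residues 1..k and the bond is cut between residues k
#' and k+1.
#'
#' @param path Path to the table.
#' @return Data frame with columns `protein_id`, `has_signal`,
#'   `cleavage_after` (`NA` when no signal), `score`.
#' @export
parse_signal_table <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), has_signal = logical(),
                      cleavage_after = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    stop("signal table line ", which(nf < 4L)[1L],
         ": expected 4 tab-delimited fields", call. = FALSE)
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  has <- toupper(m[, 2L]) %in% c("Y", "YES", "TRUE", "1")
  cleave <- suppressWarnings(as.integer(m[, 3L]))
  if (any(has & is.na(cleave))) {
    stop("signal table line ", which(has & is.na(cleave))[1L],
         ": signal predicted but no cleavage position", call. = FALSE)
  }
  if (any(has & cleave < 1L, na.rm = TRUE)) {
    stop("signal table: cleavage position must be >= 1", call. = FALSE)
  }
  data.frame(protein_id = m[, 1L], has_signal = has,
             cleavage_after = ifelse(has, cleave, NA_integer_),
             score = as.numeric(m[, 4L]), stringsAsFactors = FALSE)
}

#' Derive query metadata from UniProt-style FASTA headers
#'
#' Builds a metadata table from headers of the form
#' `db|ACCESSION|ENTRY Protein name OS=Organism OX=...`: the accession is
#' the middle `|` token, the protein name is the description text between
#' the entry token and `" OS="`, and the organism is the `OS=` value (up
#' to the next `XX=` tag). Headers without the `db|acc|entry` structure
#' use the whole id as accession and the whole description as name.
#'
#' @param records Data frame from [read_fasta()] (columns `id`, `desc`).
#' @return Data frame in the [read_query_meta()] layout (`lineage` empty).
#' @export
parse_toxprot_headers <- function(records) {
  acc <- vapply(records$id, function(id) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    if (length(parts) == 3L) parts[2L] else id
  }, character(1), USE.NAMES = FALSE)
  name <- sub("\\s+OS=.*$", "", records$desc)
  organism <- ifelse(grepl(" OS=", records$desc, fixed = TRUE),
                     sub("^.*\\sOS=(.*?)(\\s[A-Z]{2}=.*)?$", "\\1",
                         records$desc),
                     "")
  if (any(!nzchar(name))) {
    stop("header without a protein name for accession ",
         acc[!nzchar(name)][1L], call. = FALSE)
  }
  data.frame(accession = acc, protein_name = name, organism = organism,
             lineage = "", stringsAsFactors = FALSE)
}

#' Read the toxin-query metadata table
#'
#' Tab-delimited with a header: `accession`, `protein_name`, `organism`,
#' `lineage` (semicolon-separated, most inclusive taxon first). Protein
#' names seed the toxin groups.
#'
#' @param path Path to the table.
#' @return Data frame with those four character columns.
#' @export
read_query_meta <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("accession", "protein_name", "organism", "lineage")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("query metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$accession)) {
    stop("duplicate query accession: ",
         tab$accession[duplicated(tab$accession)][1L], call. = FALSE)
  }
  if (any(!nzchar(tab$protein_name))) {
    stop("empty protein_name for accession ",
         tab$accession[!nzchar(tab$protein_name)][1L], call. = FALSE)
  }
  tab[need]
}
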