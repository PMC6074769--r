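# FASTA reading and writing
#
# Records are plain data frames with columns `id`, `desc`, `seq`.  The parser
# is strict: duplicate ids and characters outside the declared alphabet are
# errors, never silently dropped or patched.

#' Read a FASTA file
#'
#' Parses nucleotide or protein FASTA. The record id is the header token
#' before the first whitespace; the remainder of the header line is kept as
#' the description. Sequences are uppercased and line wrapping is removed.
#'
#' @param path Path to a FASTA file (or a connection).
#' @param alphabet `"any"` accepts letters, `*` and `-` (protein, possibly
#'   gapped); `"dna"` restricts to `A`, `C`, `G`, `T`, `N` after mapping
#'   other IUPAC ambiguity codes to `N` with a warning.
#' @return A data frame with columns `id`, `desc`, `seq`. Empty input gives
#'   zero rows.
#' @export
read_fasta <- function(path, alphabet = c("any", "dna")) {
  alphabet <- match.arg(alphabet)
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("FASTA parse error: first non-empty line is not a header",
         call. = FALSE)
  }
  rec_idx <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(seq_along(headers), function(i) {
    body <- lines[rec_idx == i & !is_hdr]
    toupper(paste(gsub("[ \t]", "", body), collapse = ""))
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA record: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  if (alphabet == "dna") {
    seqs <- normalize_dna(seqs, ids)
  } else {
    bad <- regexpr("[^A-Z*-]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop(sprintf("illegal character '%s' at position %d in record '%s'",
                   substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]),
           call. = FALSE)
    }
  }
  data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
}

# Uppercase DNA cleanup: IUPAC ambiguity codes other than N become N with a
# warning; anything else is an error reporting the offending position.
normalize_dna <- function(seqs, ids) {
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d in record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]),
         call. = FALSE)
  }
  amb <- grepl("[RYSWKMBDHV]", seqs)
  if (any(amb)) {
    warning("IUPAC ambiguity codes mapped to N in: ",
            paste(ids[amb], collapse = ", "), call. = FALSE)
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  seqs
}

#' Read an assembled transcriptome
#'
#' [read_fasta()] with the DNA alphabet enforced.
#'
#' @inheritParams read_fasta
#' @return A data frame with columns `id`, `desc`, `seq`.
#' @export
read_transcriptome <- function(path) {
  read_fasta(path, alphabet = "dna")
}

#' Write records to FASTA
#'
#' Output is deterministic: fixed wrap width, header is the id followed by a
#' single space and the description when one is present.
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output file path.
#' @param width Wrap width in columns (default 60).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1L)
  con <- file(path, open = "wb")  # binary: LF on every platform
  on.exit(close(con))
  if (nrow(records) == 0L) {
    return(invisible(path))
  }
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", hdr), substring(s, starts, starts + width - 1L)),
               con, sep = "\n")
  }
  invisible(path)
}
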