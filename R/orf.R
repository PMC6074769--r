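# Six-frame translation and ORF prediction.
#
# Completeness classes follow common ORF-predictor usage:
#   complete            M ... stop, both in the transcript
#   five_prime_partial  runs in from the transcript edge without a leading M,
#                       ends at a stop
#   three_prime_partial starts at M, runs off the 3' end
#   internal            truncated at both ends
# Only the maximal extension per stop-bounded region is reported; ORFs
# nested in the same frame are suppressed.

# Standard genetic code (translation table 1).
GENETIC_CODE_1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Codon vector for one strand/frame; trailing 1-2 nt are dropped.
frame_codons <- function(seq, frame) {
  n_codons <- (nchar(seq) - frame) %/% 3L
  if (n_codons < 1L) return(character())
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  substring(seq, starts, starts + 2L)
}

codons_to_aa <- function(codons) {
  aa <- unname(GENETIC_CODE_1[codons])
  aa[is.na(aa)] <- "X"  # any codon with N (or other non-ACGT) is ambiguous
  aa
}

#' Translate a nucleotide sequence in a given frame and strand
#'
#' Stop codons are rendered `*`; codons containing `N` translate to `X`.
#' Translating frame `f` of the minus strand reads the reverse complement
#' from its own 5' end offset by `f`.
#'
#' @param seq Nucleotide string.
#' @param frame Offset 0, 1 or 2 on the reported strand.
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nuc <- function(seq, frame = 0L, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") seq <- revcomp(seq)
  paste(codons_to_aa(frame_codons(toupper(seq), frame)), collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Scans both strands and all three frame offsets; each stop-bounded region
#' yields at most one ORF (its maximal extension). Coordinates `start`/`end`
#' are 1-based inclusive on the forward strand of the transcript and include
#' the stop codon when the ORF ends at one.
#'
#' @param seq Nucleotide string (a transcript).
#' @param min_aa Minimum protein length in residues (stop excluded).
#' @param id Transcript id attached to the output rows.
#' @return Data frame with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `completeness`, `protein`, `length`, sorted by
#'   descending protein length, then strand (`+` first), then `start`.
#' @export
find_orfs <- function(seq, min_aa = 50L, id = "transcript") {
  stopifnot(is.character(seq), length(seq) == 1L, min_aa >= 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      aa <- codons_to_aa(frame_codons(w, frame))
      K <- length(aa)
      if (K == 0L) next
      stops <- which(aa == "*")
      region_start <- c(1L, stops + 1L)
      region_stop <- c(stops, NA_integer_)  # NA: runs off the 3' frame end
      for (r in seq_along(region_start)) {
        c1 <- region_start[r]
        stop_at <- region_stop[r]
        terminated <- !is.na(stop_at)
        last_prot <- if (terminated) stop_at - 1L else K
        if (c1 > last_prot) next
        at_5edge <- c1 == 1L
        if (at_5edge) {
          first <- c1
          compl <- if (aa[first] == "M") {
            if (terminated) "complete" else "three_prime_partial"
          } else {
            if (terminated) "five_prime_partial" else "internal"
          }
        } else {
          ms <- which(aa[c1:last_prot] == "M")
          if (length(ms) == 0L) next
          first <- c1 + ms[1L] - 1L
          compl <- if (terminated) "complete" else "three_prime_partial"
        }
        protein <- paste(aa[first:last_prot], collapse = "")
        if (nchar(protein) < min_aa) next
        nt_s <- frame + 3L * (first - 1L) + 1L
        nt_e <- frame + 3L * (if (terminated) stop_at else last_prot)
        if (strand == "-") {
          tmp <- nt_s
          nt_s <- L - nt_e + 1L
          nt_e <- L - tmp + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, strand = strand, frame = frame,
          start = nt_s, end = nt_e, completeness = compl,
          protein = protein, length = nchar(protein),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      completeness = character(), protein = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[lex_order(-out$length, out$strand, out$start, out$frame), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick the best ORF of a transcript
#'
#' The longest complete ORF wins; ties prefer the plus strand, then the
#' smaller start. Only when no complete ORF reaches `min_aa` is the longest
#' partial (or internal) ORF returned.
#'
#' @inheritParams find_orfs
#' @return One-row data frame as in [find_orfs()], or `NULL` when nothing
#'   reaches `min_aa`.
#' @export
best_orf <- function(seq, min_aa = 50L, id = "transcript") {
  orfs <- find_orfs(seq, min_aa = min_aa, id = id)
  if (nrow(orfs) == 0L) return(NULL)
  pool <- orfs[orfs$completeness == "complete", , drop = FALSE]
  if (nrow(pool) == 0L) pool <- orfs
  pool <- pool[lex_order(-pool$length, pool$strand, pool$start), , drop = FALSE]
  out <- pool[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
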