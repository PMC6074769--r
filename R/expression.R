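# Expression joining, TPM filtering, and tissue reports.
#
# Filtering is on TPM only and strictly greater than the cutoff (a
# transcript at exactly TPM 1.0 does not pass the default filter). With
# multiple samples a transcript passes when ANY sample exceeds the cutoff.
# FPKM is carried through reports but never filtered on.

#' Filter transcripts by maximum TPM across samples
#'
#' @param transcripts Data frame with columns `id`, `seq` (as from
#'   [read_transcriptome()]).
#' @param expr Expression records from [parse_expression_table()] (rows from
#'   several samples may be concatenated).
#' @param cutoff Keep a transcript iff its maximum TPM over all samples is
#'   strictly greater than this (default 1.0).
#' @return The passing subset of `transcripts`, input order preserved.
#'   Transcripts with no expression record are dropped, with a message
#'   giving their count.
#' @export
tpm_filter <- function(transcripts, expr, cutoff = 1.0) {
  stopifnot(cutoff >= 0)
  max_tpm <- tapply(expr$tpm, expr$transcript_id, max)
  no_rec <- !(transcripts$id %in% names(max_tpm))
  if (any(no_rec)) {
    message(sum(no_rec), " transcript(s) had no expression record and were dropped")
  }
  keep <- !no_rec & unname(max_tpm[transcripts$id]) > cutoff
  keep[is.na(keep)] <- FALSE
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group expression table
#'
#' One row per member transcript with every sample's TPM (and FPKM when any
#' FPKM was supplied), missing values rendered `NA`, rows ordered by
#' descending maximum TPM (members with no record last, by id).
#'
#' @param group A `toxin_group` from [assign_groups()].
#' @param expr Expression records.
#' @return Data frame: `transcript_id`, one `tpm_<sample>` column per
#'   sample, and matching `fpkm_<sample>` columns when FPKM is present.
#' @export
group_expression_table <- function(group, expr) {
  members <- group$members$transcript_id
  samples <- lex_sort(unique(expr$sample))
  have_fpkm <- any(!is.na(expr$fpkm))
  out <- data.frame(transcript_id = members, stringsAsFactors = FALSE)
  for (s in samples) {
    sub <- expr[expr$sample == s, , drop = FALSE]
    out[[paste0("tpm_", s)]] <- sub$tpm[match(members, sub$transcript_id)]
    if (have_fpkm) {
      out[[paste0("fpkm_", s)]] <- sub$fpkm[match(members, sub$transcript_id)]
    }
  }
  tpm_cols <- paste0("tpm_", samples)
  max_tpm <- do.call(pmax, c(out[tpm_cols], list(na.rm = TRUE)))
  max_tpm[!is.finite(max_tpm)] <- -Inf
  out <- out[lex_order(-max_tpm, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tissue expression report for candidate transcripts
#'
#' For each candidate, reports every sample's TPM, the sample of maximal
#' expression, and a highlight flag when the maximum exceeds
#' `highlight_tpm` (default 100, the usual "highly expressed" bar in venom
#' gland screens). Ties in the maximum pick the lexicographically first
#' sample and set `tie`.
#'
#' @param candidate_ids Character vector of transcript ids.
#' @param expr Expression records covering at least one sample; a candidate
#'   missing from a sample counts as TPM 0 there.
#' @param highlight_tpm Highlight threshold (strictly greater than).
#' @return Data frame: `transcript_id`, `tpm_<sample>` columns,
#'   `max_sample`, `max_tpm`, `tie`, `highlight`.
#' @export
tissue_report <- function(candidate_ids, expr, highlight_tpm = 100) {
  samples <- lex_sort(unique(expr$sample))
  stopifnot(length(samples) >= 1L)
  out <- data.frame(transcript_id = candidate_ids, stringsAsFactors = FALSE)
  tpm <- matrix(0, length(candidate_ids), length(samples),
                dimnames = list(NULL, samples))
  for (s in samples) {
    sub <- expr[expr$sample == s, , drop = FALSE]
    v <- sub$tpm[match(candidate_ids, sub$transcript_id)]
    tpm[, s] <- ifelse(is.na(v), 0, v)
    out[[paste0("tpm_", s)]] <- tpm[, s]
  }
  max_tpm <- apply(tpm, 1L, max)
  out$max_sample <- vapply(seq_along(candidate_ids), function(i) {
    samples[which(tpm[i, ] == max_tpm[i])[1L]]
  }, character(1))
  out$max_tpm <- max_tpm
  out$tie <- vapply(seq_along(candidate_ids), function(i) {
    sum(tpm[i, ] == max_tpm[i]) > 1L
  }, logical(1))
  out$highlight <- max_tpm > highlight_tpm
  out
}
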