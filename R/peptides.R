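# Signal / mature peptide handling.
#
# External predictions (parsed from the short tabular format) always take
# precedence; the rule-based predictor below exists so the pipeline and its
# tests run with no external binary. It encodes the textbook tripartite
# signal-peptide architecture (charged n-region, hydrophobic h-region,
# small-residue c-region ending in an A-X-A-like motif).

SP_HYDROPHOBIC <- c("A", "I", "L", "F", "V", "M", "W", "C")
SP_SMALL <- c("A", "G", "S", "C", "T")

#' Split a precursor into signal and mature peptides
#'
#' "Cleavage after k" cuts the bond between residues k and k+1: the signal
#' is residues 1..k, the mature peptide the remainder.
#'
#' @param protein Precursor amino-acid string.
#' @param annotation One-row data frame (or list) with `protein_id`,
#'   `has_signal`, `cleavage_after` as produced by [parse_signal_table()] or
#'   [fallback_signal_predict()].
#' @param protein_id Id the annotation must refer to.
#' @return List with `protein_id`, `signal` (`NA` when none) and `mature`;
#'   `signal` and `mature` always concatenate back to the precursor.
#' @export
split_precursor <- function(protein, annotation, protein_id = annotation$protein_id) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  if (!identical(as.character(annotation$protein_id), as.character(protein_id))) {
    stop("annotation is for '", annotation$protein_id,
         "', not '", protein_id, "'", call. = FALSE)
  }
  if (!isTRUE(as.logical(annotation$has_signal))) {
    return(list(protein_id = protein_id, signal = NA_character_,
                mature = protein))
  }
  k <- as.integer(annotation$cleavage_after)
  if (is.na(k) || k < 1L) {
    stop("signal annotation without a valid cleavage position", call. = FALSE)
  }
  if (k >= nchar(protein)) {
    stop("cleavage position ", k, " must be < protein length ",
         nchar(protein), call. = FALSE)
  }
  list(protein_id = protein_id,
       signal = substr(protein, 1L, k),
       mature = substr(protein, k + 1L, nchar(protein)))
}

#' Rule-based signal-peptide prediction
#'
#' Deterministic fallback used when no external prediction table is
#' supplied. For each candidate signal length k in 12..35 it requires:
#' at least one K/R among residues 1..5 (n-region); a contiguous stretch of
#' at least six hydrophobic residues (`A I L F V M W C`) entirely within
#' residues 3..k-3 (h-region); and small residues (`A G S C T`) at positions
#' k-2 and k (A-X-A-like c-region). The smallest qualifying k is the
#' cleavage site; the score is the h-region run length / 6, capped at 1.
#' Proteins shorter than 15 residues or not starting with M never have a
#' signal.
#'
#' @param protein Amino-acid string.
#' @param protein_id Identifier for the returned annotation.
#' @return One-row data frame in the [parse_signal_table()] layout.
#' @export
fallback_signal_predict <- function(protein, protein_id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  no <- data.frame(protein_id = protein_id, has_signal = FALSE,
                   cleavage_after = NA_integer_, score = 0,
                   stringsAsFactors = FALSE)
  n <- nchar(protein)
  if (n < 15L || substr(protein, 1L, 1L) != "M") return(no)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!any(aa[1:5] %in% c("K", "R"))) return(no)
  hydro <- aa %in% SP_HYDROPHOBIC
  for (k in 12:min(35L, n - 1L)) {
    if (!(aa[k - 2L] %in% SP_SMALL && aa[k] %in% SP_SMALL)) next
    run <- longest_run(hydro[3:(k - 3L)])
    if (run >= 6L) {
      return(data.frame(protein_id = protein_id, has_signal = TRUE,
                        cleavage_after = k, score = min(1, run / 6),
                        stringsAsFactors = FALSE))
    }
  }
  no
}

longest_run <- function(flags) {
  if (length(flags) == 0L || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Predict signals for a set of proteins, honoring external annotations
#'
#' @param proteins Named character vector (names are protein ids).
#' @param external Optional data frame from [parse_signal_table()]; rows
#'   matching a protein id override the fallback predictor.
#' @return Data frame, one row per protein, in the [parse_signal_table()]
#'   layout plus a `source` column (`"external"` or `"fallback"`).
#' @export
predict_signals <- function(proteins, external = NULL) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(pid) {
    if (!is.null(external) && pid %in% external$protein_id) {
      row <- external[external$protein_id == pid, , drop = FALSE][1L, ]
      row$source <- "external"
      return(row[c("protein_id", "has_signal", "cleavage_after", "score",
                   "source")])
    }
    row <- fallback_signal_predict(proteins[[pid]], pid)
    row$source <- "fallback"
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
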