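# Toxin-group assignment and reciprocal E-value screening.
#
# Groups are keyed by the query protein NAME (not accession): queries that
# share a name merge, and a transcript joins every group it hits, because
# related toxin families legitimately attract the same candidates. Names
# can carry misleading lineage labels (a "conophysin" group may hold
# neurophysins); grouping deliberately does not try to fix that.

E_FLOOR <- 1e-200  # zero E-values are floored here before log10

#' Sanitize a toxin group name into a filesystem-safe key
#'
#' Spaces and `/` become `_`; characters other than alphanumerics, `-`, `_`
#' and `.` are stripped; case is preserved.
#'
#' @param protein_name Non-empty protein name.
#' @return The sanitized key.
#' @export
normalize_group_name <- function(protein_name) {
  stopifnot(is.character(protein_name))
  if (any(!nzchar(protein_name))) stop("empty protein name", call. = FALSE)
  key <- gsub("[ /]", "_", protein_name)
  key <- gsub("[^A-Za-z0-9_.-]", "", key)
  if (any(!nzchar(key))) {
    stop("protein name sanitizes to an empty key: ",
         protein_name[!nzchar(key)][1L], call. = FALSE)
  }
  key
}

# Map distinct display names to unique keys; names colliding after
# sanitization get deterministic numeric suffixes in sorted display order.
make_group_keys <- function(display_names) {
  display_names <- lex_sort(unique(display_names))
  keys <- normalize_group_name(display_names)
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    keys[idx] <- paste0(k, "_", seq_along(idx))
  }
  stats::setNames(keys, display_names)
}

# Order hits best-first: minimum E-value, then maximum bit score, then
# lexicographic query accession.
order_hits_best_first <- function(hits) {
  lex_order(hits$evalue, -hits$bit_score, hits$query_id)
}

#' Partition passing hits into toxin groups
#'
#' Hits with `evalue <= evalue_cutoff` are grouped by the protein name of
#' their query. With `multi_group = TRUE` (default) a transcript joins every
#' group it hits; otherwise only the group holding its single best hit.
#' Within a (group, transcript) pair the stored best hit minimizes E-value,
#' breaking ties by maximum bit score then lexicographic accession.
#'
#' @param hits Data frame from [parse_blast_tab()].
#' @param meta Data frame from [read_query_meta()]; every hit's `query_id`
#'   must appear in `meta$accession`.
#' @param evalue_cutoff Inclusion threshold (hits at the cutoff pass).
#' @param multi_group Allow transcripts in several groups.
#' @return A list of `toxin_group` objects sorted by key; each has fields
#'   `name` (key), `display_name`, `queries` (accessions) and `members`
#'   (data frame: `transcript_id` plus its best hit's fields).
#' @export
assign_groups <- function(hits, meta, evalue_cutoff = 1e-6,
                          multi_group = TRUE) {
  stopifnot(evalue_cutoff > 0)
  unknown <- setdiff(hits$query_id, meta$accession)
  if (length(unknown) > 0L) {
    stop("hit(s) reference unknown query accession(s): ",
         paste(lex_sort(unknown), collapse = ", "), call. = FALSE)
  }
  pass <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(pass) == 0L) return(list())
  pass$group_name <- meta$protein_name[match(pass$query_id, meta$accession)]
  if (!multi_group) {
    pass <- pass[order_hits_best_first(pass), , drop = FALSE]
    best_group <- tapply(pass$group_name, pass$subject_id, `[`, 1L)
    pass <- pass[pass$group_name == best_group[pass$subject_id], ,
                 drop = FALSE]
  }
  keys <- make_group_keys(pass$group_name)
  groups <- lapply(names(keys), function(dn) {
    gh <- pass[pass$group_name == dn, , drop = FALSE]
    gh <- gh[order_hits_best_first(gh), , drop = FALSE]
    members <- gh[!duplicated(gh$subject_id), , drop = FALSE]
    members <- members[lex_order(members$subject_id), , drop = FALSE]
    members <- data.frame(transcript_id = members$subject_id,
                          members[setdiff(names(members),
                                          c("subject_id", "group_name"))],
                          stringsAsFactors = FALSE)
    rownames(members) <- NULL
    structure(list(name = unname(keys[dn]), display_name = dn,
                   queries = lex_sort(unique(
                     meta$accession[meta$protein_name == dn])),
                   members = members),
              class = "toxin_group")
  })
  groups[lex_order(vapply(groups, `[[`, character(1), "name"))]
}

#' @export
print.toxin_group <- function(x, ...) {
  cat(sprintf("<toxin_group> %s ('%s'): %d queries, %d member transcripts\n",
              x$name, x$display_name, length(x$queries), nrow(x$members)))
  invisible(x)
}

#' Classify one translated candidate by the reciprocal E-value rule
#'
#' A protein is a `candidate` when its best toxin E-value beats its best
#' non-toxin E-value by at least `margin_orders` orders of magnitude (or
#' when it has no non-toxin hit at all); `rejected` otherwise;
#' `unevaluated` when it has no toxin hit. Zero E-values are floored at
#' 1e-200 before taking logs.
#'
#' @param protein_id Identifier attached to the verdict.
#' @param toxin_hits,nontoxin_hits Hit data frames (possibly zero rows) with
#'   at least `query_id`, `evalue`, `bit_score` columns.
#' @param margin_orders Required advantage in orders of magnitude
#'   (default 0: any strictly-better-or-equal... see Details).
#' @details With the default `margin_orders = 0` a tie in E-values still
#'   passes (`log10` difference 0 >= 0); require a strictly positive margin
#'   to demand a real advantage.
#' @return One-row data frame: `protein_id`, `best_toxin_acc`,
#'   `best_toxin_evalue`, `best_nontoxin_acc`, `best_nontoxin_evalue`,
#'   `margin_orders`, `verdict`.
#' @export
classify_candidate <- function(protein_id, toxin_hits, nontoxin_hits,
                               margin_orders = 0) {
  stopifnot(margin_orders >= 0)
  best_of <- function(h) {
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    if (any(h$evalue < 0)) stop("negative E-value", call. = FALSE)
    h[order_hits_best_first(h)[1L], , drop = FALSE]
  }
  bt <- best_of(toxin_hits)
  bn <- best_of(nontoxin_hits)
  margin <- NA_real_
  if (is.null(bt)) {
    verdict <- "unevaluated"
  } else if (is.null(bn)) {
    verdict <- "candidate"
  } else {
    margin <- log10(max(bn$evalue, E_FLOOR)) - log10(max(bt$evalue, E_FLOOR))
    verdict <- if (margin >= margin_orders) "candidate" else "rejected"
  }
  data.frame(
    protein_id = protein_id,
    best_toxin_acc = if (is.null(bt)) NA_character_ else bt$query_id,
    best_toxin_evalue = if (is.null(bt)) NA_real_ else bt$evalue,
    best_nontoxin_acc = if (is.null(bn)) NA_character_ else bn$query_id,
    best_nontoxin_evalue = if (is.null(bn)) NA_real_ else bn$evalue,
    margin_orders = margin,
    verdict = verdict,
    stringsAsFactors = FALSE)
}

#' Group and transcript counts across E-value cutoffs
#'
#' Mirrors running the grouping at a stringent and a lenient threshold:
#' one row per cutoff with the number of groups and of distinct member
#' transcripts at that cutoff.
#'
#' @inheritParams assign_groups
#' @param cutoffs Non-empty numeric vector of E-value cutoffs.
#' @return Data frame with columns `cutoff`, `n_groups`, `n_transcripts`.
#' @export
stringency_sweep <- function(hits, meta, cutoffs) {
  stopifnot(length(cutoffs) >= 1L)
  rows <- lapply(cutoffs, function(ct) {
    groups <- assign_groups(hits, meta, evalue_cutoff = ct)
    data.frame(cutoff = ct, n_groups = length(groups),
               n_transcripts = length(unique(unlist(lapply(groups, function(g)
                 g$members$transcript_id)))))
  })
  do.call(rbind, rows)
}
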