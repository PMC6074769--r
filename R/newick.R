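# Newick serialization for gene trees.
#
# Trees are `ape` "phylo" objects throughout the package; the writer is
# canonical so identical trees always serialize to identical bytes:
# children are ordered by the lexicographically smallest leaf label in their
# subtree and branch lengths are printed with six decimals.

#' Serialize a tree to canonical Newick
#'
#' @param tree An [ape::ape-package] `phylo` object with branch lengths.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when `path` is given).
#' @details Label escaping convention: spaces become underscores; labels
#'   containing structural Newick characters (`(),:;[]'`) are wrapped in
#'   single quotes with embedded quotes doubled.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  esc <- function(lab) {
    lab <- gsub(" ", "_", lab, fixed = TRUE)
    if (grepl("[(),:;\\[\\]']", lab)) {
      lab <- paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
    }
    lab
  }
  min_leaf <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    labs <- vapply(tree$edge[kids[[as.character(node)]], 2L],
                   min_leaf, character(1))
    lex_sort(labs)[1L]
  }
  emit <- function(node) {
    if (node <= ntip) return(esc(tree$tip.label[node]))
    ek <- kids[[as.character(node)]]
    ord <- lex_order(vapply(tree$edge[ek, 2L], min_leaf, character(1)))
    parts <- vapply(ek[ord], function(e) {
      child <- emit(tree$edge[e, 2L])
      if (has_len) paste0(child, ":", sprintf("%.6f", tree$edge.length[e]))
      else child
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  txt <- paste0(emit(root), ";")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(txt)
}

#' Parse a Newick string or file into a `phylo` tree
#'
#' @param text Newick string; or use `path`.
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(read_input_lines(path), collapse = "")
  }
  ape::read.tree(text = text)
}

# Two-leaf degenerate "tree": the pairwise distance split evenly across the
# two pendant branches. NJ proper needs n >= 3.
two_leaf_tree <- function(labels, dist) {
  stopifnot(length(labels) == 2L, dist >= 0)
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2L, byrow = TRUE),
                 edge.length = rep(dist / 2, 2L),
                 tip.label = labels, Nnode = 1L),
            class = "phylo", order = "cladewise")
}
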