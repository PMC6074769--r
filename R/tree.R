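# Evolutionary distances and neighbor joining.
#
# Classic NJ (Saitou-Nei / Studier-Keppler): iteratively join the pair
# minimizing Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with the
# standard two-point branch-length formulas. Ties in Q are broken by the
# lexicographically smallest pair of cluster representatives (a cluster is
# represented by its smallest leaf label), so results are deterministic.
# Negative branch-length estimates are clamped to zero with the deficit
# moved to the sister branch, preserving the pair's summed length. The last
# three lineages join at a single (possibly multifurcating) node, so the
# result is an unrooted tree.

#' Pairwise p-distances (or Poisson-corrected distances) from an alignment
#'
#' Pairwise deletion: columns where either row has a gap are skipped for
#' that pair. `p = mismatches / compared columns`; the Poisson correction is
#' `d = -ln(1 - p)` with `p >= 1` floored at 0.999 (with a warning).
#'
#' @param aln Named character vector of equal-width gapped rows (at least
#'   two), as produced by [progressive_msa()].
#' @param correction `"none"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with the row ids as dimnames.
#' @export
p_distance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(length(aln) >= 2L, !is.null(names(aln)))
  widths <- nchar(aln)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows differ in width", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(chars) <- names(aln)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", names(aln)[i], "' and '",
             names(aln)[j], "'", call. = FALSE)
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      if (correction == "poisson") {
        if (p >= 1) {
          warning("p-distance >= 1 between '", names(aln)[i], "' and '",
                  names(aln)[j], "'; floored at 0.999 before correction",
                  call. = FALSE)
          p <- 0.999
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# Shared NJ engine. Returns the recursive node structure of the unrooted
# tree plus the cluster-join schedule (survivor representative first).
nj_core <- function(D) {
  labels <- rownames(D)
  stopifnot(!is.null(labels), !anyDuplicated(labels), isSymmetric(unname(D)))
  n <- length(labels)
  nodes <- lapply(labels, function(l) list(leaf = TRUE, label = l))
  names(nodes) <- labels
  joins <- list()
  while (n > 3L) {
    r <- rowSums(D)
    reps <- rownames(D)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2L) * D[i, j] - r[i] - r[j]
        pair <- lex_sort(c(reps[i], reps[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(q = q, i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2L))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    ri <- reps[i]; rj <- reps[j]
    surv <- best$pair[1L]
    other <- if (surv == ri) rj else ri
    new_node <- list(leaf = FALSE,
                     children = list(list(node = nodes[[ri]], len = li),
                                     list(node = nodes[[rj]], len = lj)))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    rownames(D)[n - 1L] <- colnames(D)[n - 1L] <- surv
    nodes[[other]] <- NULL
    nodes[[surv]] <- new_node
    joins[[length(joins) + 1L]] <- c(surv, other)
    n <- n - 1L
  }
  reps <- rownames(D)
  ord <- lex_order(reps)
  if (n == 3L) {
    a <- ord[1L]; b <- ord[2L]; cc <- ord[3L]
    la <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
    lb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
    lc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
    root <- list(leaf = FALSE, children = list(
      list(node = nodes[[reps[a]]], len = max(la, 0)),
      list(node = nodes[[reps[b]]], len = max(lb, 0)),
      list(node = nodes[[reps[cc]]], len = max(lc, 0))))
    final_joins <- list(c(lex_sort(reps)[1L], lex_sort(reps)[2L]),
                        c(lex_sort(reps)[1L], lex_sort(reps)[3L]))
  } else {  # n == 2 (only reachable from a 2x2 input)
    root <- list(leaf = FALSE, children = list(
      list(node = nodes[[reps[ord[1L]]]], len = D[1L, 2L] / 2),
      list(node = nodes[[reps[ord[2L]]]], len = D[1L, 2L] / 2)))
    final_joins <- list(lex_sort(reps))
  }
  list(root = root, joins = c(joins, final_joins))
}

#' Neighbor-joining tree from a distance matrix
#'
#' On an additive (tree-realizable) matrix this recovers the generating
#' unrooted topology and branch lengths exactly.
#'
#' @param D Symmetric distance matrix with unique labels as dimnames and at
#'   least three rows.
#' @return An unrooted `phylo` tree; leaf labels are the matrix labels.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dim(D)) || nrow(D) < 3L) {
    stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  build_phylo(nj_core(D)$root)
}

# Cluster-merge schedule for the progressive aligner's guide: NJ joins,
# then the final two or three clusters merged in lexicographic order.
nj_join_schedule <- function(D) {
  if (nrow(D) == 2L) return(list(lex_sort(rownames(D))))
  nj_core(D)$joins
}

# Convert the recursive node structure into an ape "phylo" object.
build_phylo <- function(root) {
  tips <- character()
  collect <- function(node) {
    if (isTRUE(node$leaf)) tips <<- c(tips, node$label)
    else for (ch in node$children) collect(ch$node)
  }
  collect(root)
  ntip <- length(tips)
  tip_id <- stats::setNames(seq_len(ntip), tips)
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric()
  next_internal <- ntip + 2L
  walk <- function(node, my_id) {  # preorder: parents precede children
    for (ch in node$children) {
      if (isTRUE(ch$node$leaf)) {
        cid <- tip_id[[ch$node$label]]
      } else {
        cid <- next_internal
        next_internal <<- next_internal + 1L
      }
      edges <<- rbind(edges, c(my_id, cid))
      lens <<- c(lens, unname(ch$len))
      if (!isTRUE(ch$node$leaf)) walk(ch$node, cid)
    }
  }
  walk(root, ntip + 1L)
  structure(list(edge = edges, edge.length = lens, tip.label = tips,
                 Nnode = next_internal - ntip - 1L),
            class = "phylo", order = "cladewise")
}
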