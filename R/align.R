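# Pairwise and progressive protein alignment.
#
# The pairwise engine is global Needleman-Wunsch with affine gaps (Gotoh's
# three-state recursion). Gap cost convention: a gap of length g costs
# gap_open + (g - 1) * gap_extend, i.e. the opening position already pays
# gap_open. Traceback is deterministic with tie order diagonal > up > left
# ("up" consumes a residue of the first sequence).
#
# The multiple aligner is progressive: a neighbor-joining guide built on
# 3-mer cosine distances fixes the merge order, profiles are merged by
# profile-profile Needleman-Wunsch with mean-of-pairs column scoring, and
# once a gap column is inserted it is never removed.

#' Load a substitution matrix from the bundled plain-text format
#'
#' @param name Matrix name; `"BLOSUM62"` ships with the package.
#' @param path Optional explicit path to a matrix file in the standard
#'   whitespace-separated layout with a header row of residues and one
#'   labeled row per residue; `#` lines are comments.
#' @return Numeric matrix with residue dimnames.
#' @export
load_score_matrix <- function(name = "BLOSUM62", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", paste0(name, ".txt"),
                        package = "toxtriage", mustWork = TRUE)
  }
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  m <- t(vapply(body, function(p) as.numeric(p[-1L]), numeric(length(cols))))
  dimnames(m) <- list(rows, cols)
  m
}

the_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_score_matrix("BLOSUM62")
    cache
  }
})

#' Global pairwise alignment with affine gap penalties
#'
#' @param a,b Non-empty protein strings.
#' @param matrix Substitution matrix (default bundled BLOSUM62).
#' @param gap_open Score for the first position of a gap (negative).
#' @param gap_extend Score for each further gapped position (negative).
#' @return List with `score` and `alignment`, a character vector of the two
#'   gapped strings.
#' @export
nw_align <- function(a, b, matrix = NULL, gap_open = -10, gap_extend = -1) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b),
            gap_open < 0, gap_extend < 0)
  smat <- if (is.null(matrix)) the_blosum62() else matrix
  rm(matrix)  # unshadow base::matrix
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  miss <- setdiff(c(av, bv), rownames(smat))
  if (length(miss) > 0L) {
    stop("residue(s) absent from substitution matrix: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  sub <- smat[av, bv, drop = FALSE]
  res <- gotoh(sub, gap_open, gap_extend)
  aln_a <- paste(ifelse(res$path[, 1L] > 0L, av[res$path[, 1L]], "-"),
                 collapse = "")
  aln_b <- paste(ifelse(res$path[, 2L] > 0L, bv[res$path[, 2L]], "-"),
                 collapse = "")
  list(score = res$score, alignment = c(aln_a, aln_b))
}

# Core affine-gap DP on a precomputed column-pair score matrix `sub`
# (n x m). Returns the optimal score and the traceback path as a two-column
# matrix of row/col indices (0 = gap). State M = diagonal, X = gap in the
# second sequence (consumes a row, "up"), Y = gap in the first ("left").
gotoh <- function(sub, go, ge) {
  n <- nrow(sub); m <- ncol(sub)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- go + ge * (0:(n - 1L))
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- go + ge * (0:(m - 1L))
  # predecessor state codes: 1 = M, 2 = X, 3 = Y (also the tie priority)
  pM <- matrix(0L, n + 1L, m + 1L)
  pX <- matrix(0L, n + 1L, m + 1L)
  pY <- matrix(0L, n + 1L, m + 1L)
  pX[2:(n + 1L), 1L] <- 2L; pX[2L, 1L] <- 1L
  pY[1L, 2:(m + 1L)] <- 3L; pY[1L, 2L] <- 1L
  pick <- function(vm, vx, vy) {
    if (vm >= vx && vm >= vy) list(v = vm, s = 1L)
    else if (vx >= vy) list(v = vx, s = 2L)
    else list(v = vy, s = 3L)
  }
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      d <- pick(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      M[i, j] <- d$v + sub[i - 1L, j - 1L]; pM[i, j] <- d$s
      u <- pick(M[i - 1L, j] + go, X[i - 1L, j] + ge, Y[i - 1L, j] + go)
      X[i, j] <- u$v; pX[i, j] <- u$s
      l <- pick(M[i, j - 1L] + go, X[i, j - 1L] + go, Y[i, j - 1L] + ge)
      Y[i, j] <- l$v; pY[i, j] <- l$s
    }
  }
  fin <- pick(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  i <- n + 1L; j <- m + 1L; s <- fin$s
  path <- matrix(0L, 0L, 2L)
  while (i > 1L || j > 1L) {
    if (s == 1L) {
      path <- rbind(c(i - 1L, j - 1L), path)
      s <- pM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (s == 2L) {
      path <- rbind(c(i - 1L, 0L), path)
      s <- pX[i, j]; i <- i - 1L
    } else {
      path <- rbind(c(0L, j - 1L), path)
      s <- pY[i, j]; j <- j - 1L
    }
  }
  list(score = fin$v, path = path)
}

# 3-mer count vector cosine distance between two sequences; sequences with
# no 3-mer (length < 3) are maximally distant from everything.
kmer_cosine_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      num <- sum(as.numeric(ci[shared]) * as.numeric(cj[shared]))
      den <- sqrt(sum(as.numeric(ci)^2)) * sqrt(sum(as.numeric(cj)^2))
      d[i, j] <- d[j, i] <- if (den == 0) 1 else 1 - num / den
    }
  }
  d
}

#' Progressive multiple alignment of protein sequences
#'
#' @param seqs Named character vector of at least two protein strings.
#' @param matrix Substitution matrix (default bundled BLOSUM62).
#' @param gap_open,gap_extend Affine gap scores as in [nw_align()].
#' @return Named character vector of gapped rows, all the same width, in
#'   the input order; ungapping any row recovers its input exactly.
#' @export
progressive_msa <- function(seqs, matrix = NULL, gap_open = -10,
                            gap_extend = -1) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  smat <- if (is.null(matrix)) the_blosum62() else matrix
  rm(matrix)  # unshadow base::matrix
  if (length(seqs) == 2L) {
    pw <- nw_align(seqs[[1L]], seqs[[2L]], smat, gap_open, gap_extend)
    return(stats::setNames(pw$alignment, names(seqs)))
  }
  profiles <- lapply(names(seqs), function(nm) {
    matrix(strsplit(seqs[[nm]], "", fixed = TRUE)[[1]], nrow = 1L,
           dimnames = list(nm, NULL))
  })
  names(profiles) <- names(seqs)
  d <- kmer_cosine_dist(seqs)
  for (join in nj_join_schedule(d)) {
    merged <- profile_nw(profiles[[join[1L]]], profiles[[join[2L]]],
                         smat, gap_open, gap_extend)
    profiles[[join[1L]]] <- merged
    profiles[[join[2L]]] <- NULL
  }
  final <- profiles[[1L]]
  rows <- apply(final, 1L, paste, collapse = "")
  stats::setNames(rows[names(seqs)], names(seqs))
}

# Merge two profile matrices by affine NW on mean-of-pairs column scores;
# gap-vs-residue pairs contribute nothing to the mean.
profile_nw <- function(pa, pb, smat, go, ge) {
  col_score <- function(ca, cb) {
    ra <- ca[ca != "-"]; rb <- cb[cb != "-"]
    if (length(ra) == 0L || length(rb) == 0L) return(0)
    mean(smat[ra, rb])
  }
  sub <- outer(seq_len(ncol(pa)), seq_len(ncol(pb)),
               Vectorize(function(i, j) col_score(pa[, i], pb[, j])))
  res <- gotoh(matrix(sub, ncol(pa), ncol(pb)), go, ge)
  gap_a <- matrix("-", nrow(pa), 1L)
  gap_b <- matrix("-", nrow(pb), 1L)
  cols <- lapply(seq_len(nrow(res$path)), function(k) {
    i <- res$path[k, 1L]; j <- res$path[k, 2L]
    rbind(if (i > 0L) pa[, i, drop = FALSE] else gap_a,
          if (j > 0L) pb[, j, drop = FALSE] else gap_b)
  })
  out <- do.call(cbind, cols)
  rownames(out) <- c(rownames(pa), rownames(pb))
  out
}
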