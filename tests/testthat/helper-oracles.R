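# Independent oracles and fuzz generators shared across the suite.
# The oracles deliberately avoid the package's own primitives: translation
# and reverse complementation come from seqinr, tree comparison from
# phangorn, Newick parsing from ape.

# ---- brute-force six-frame ORF scanner ---------------------------------

oracle_revcomp <- function(seq) {
  paste(rev(seqinr::comp(strsplit(seq, "")[[1]], forceToLower = FALSE,
                         ambiguous = FALSE)), collapse = "")
}

# Enumerates, for every strand/frame, every stop-or-edge terminator, the
# maximal allowed start (the frame edge, or the first downstream M when a
# stop precedes the region), classifies it, and keeps ORFs >= min_aa.
oracle_orfs <- function(seq, min_aa, id = "transcript") {
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      aa <- seqinr::translate(strsplit(w, "")[[1]], frame = frame)
      K <- length(aa)
      if (K == 0L) next
      stops <- which(aa == "*")
      terminators <- c(stops, NA)  # NA = runs off the 3' frame edge
      for (t in seq_along(terminators)) {
        term <- terminators[t]
        rs <- if (t == 1L) 1L else stops[t - 1L] + 1L
        prot_end <- if (is.na(term)) K else term - 1L
        if (rs > prot_end) next
        if (rs == 1L) {
          st <- 1L
        } else {
          ms <- which(aa[rs:prot_end] == "M")
          if (length(ms) == 0L) next
          st <- rs + ms[1L] - 1L
        }
        protein <- paste(aa[st:prot_end], collapse = "")
        if (nchar(protein) < min_aa) next
        compl <- if (aa[st] == "M") {
          if (is.na(term)) "three_prime_partial" else "complete"
        } else {
          if (is.na(term)) "internal" else "five_prime_partial"
        }
        ns <- frame + 3L * (st - 1L) + 1L
        ne <- frame + 3L * (if (is.na(term)) prot_end else term)
        if (strand == "-") {
          hold <- ns; ns <- L - ne + 1L; ne <- L - hold + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, strand = strand, frame = frame,
          start = ns, end = ne, completeness = compl, protein = protein,
          length = nchar(protein), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      completeness = character(), protein = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# canonical row ordering so ORF sets can be compared as data frames
orf_canonical <- function(orfs) {
  orfs <- orfs[order(orfs$strand, orfs$frame, orfs$start, orfs$end), ,
               drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# ---- exhaustive global-alignment scorer --------------------------------

# Best affine-gap global alignment score by enumerating every monotone
# alignment path (no memoization on scores: plain recursion over the path
# prefix tree). Gap cost: open + (g - 1) * extend per run.
oracle_nw_score <- function(a, b, smat, go, ge) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, last) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la) {
      best <- max(best, (if (last == "up") ge else go) + rec(i + 1L, j, "up"))
    }
    if (j < lb) {
      best <- max(best, (if (last == "left") ge else go) +
                    rec(i, j + 1L, "left"))
    }
    if (i < la && j < lb) {
      best <- max(best, smat[av[i + 1L], bv[j + 1L]] +
                    rec(i + 1L, j + 1L, "diag"))
    }
    best
  }
  rec(0L, 0L, "none")
}

# ---- random input generators -------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                         "G", "H", "I", "L", "K", "M", "F",
                                         "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_fasta_records <- function(n_max = 6L) {
  n <- sample.int(n_max, 1L)
  data.frame(
    id = sprintf("seq%02d_%s", seq_len(n),
                 replicate(n, rand_protein(4, LETTERS))),
    desc = replicate(n, if (runif(1) < 0.5) "" else
      paste(sample(letters, 8, replace = TRUE), collapse = "")),
    seq = replicate(n, rand_dna(sample(5:200, 1L))),
    stringsAsFactors = FALSE)
}

# random 12-column hit table against a random query panel
rand_hit_table <- function(n_queries = 6L, n_transcripts = 12L,
                           n_hits = 30L, n_names = 4L) {
  accs <- sprintf("Q%03d", seq_len(n_queries))
  names_pool <- sprintf("Toxin family %d", seq_len(n_names))
  meta <- data.frame(accession = accs,
                     protein_name = sample(names_pool, n_queries,
                                           replace = TRUE),
                     organism = "Testus organismus",
                     lineage = "Eukaryota;Metazoa",
                     stringsAsFactors = FALSE)
  tids <- sprintf("TR%03d", seq_len(n_transcripts))
  hits <- data.frame(
    query_id = sample(accs, n_hits, replace = TRUE),
    subject_id = sample(tids, n_hits, replace = TRUE),
    pct_identity = round(runif(n_hits, 20, 100), 1),
    aln_len = sample(30:300, n_hits, replace = TRUE),
    mismatches = sample(0:50, n_hits, replace = TRUE),
    gap_opens = sample(0:3, n_hits, replace = TRUE),
    q_start = sample(1:10, n_hits, replace = TRUE),
    q_end = sample(50:300, n_hits, replace = TRUE),
    s_start = sample(1:500, n_hits, replace = TRUE),
    s_end = sample(1:500, n_hits, replace = TRUE),
    evalue = 10^runif(n_hits, -60, 0),
    bit_score = round(runif(n_hits, 20, 300), 1),
    stringsAsFactors = FALSE)
  hits$s_end[hits$s_end == hits$s_start] <-
    hits$s_end[hits$s_end == hits$s_start] + 1L
  list(hits = hits, meta = meta)
}

# fresh temp dir path (not yet created)
fresh_dir <- function() {
  file.path(tempfile("toxtriage_"))
}

expect_same_files <- function(dir_a, dir_b) {
  fa <- sort(list.files(dir_a, recursive = TRUE))
  fb <- sort(list.files(dir_b, recursive = TRUE))
  expect_identical(fa, fb)
  ma <- unname(tools::md5sum(file.path(dir_a, fa)))
  mb <- unname(tools::md5sum(file.path(dir_b, fb)))
  expect_identical(ma, mb)
}
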