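# shared internal helpers

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and an index,
# kept within the 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 10007 + i * 97) %% 2147483581L)
}

# C-locale lexicographic sort, stable across platforms and locales.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Read all lines of a file or textConnection-able input.
read_input_lines <- function(path) {
  if (inherits(path, "connection")) {
    return(readLines(path, warn = FALSE))
  }
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  readLines(path, warn = FALSE)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq A single nucleotide string (A, C, G, T, N).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}
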