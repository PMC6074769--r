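test_that("read_fasta parses headers, joins wrapped lines and uppercases", {
  tf <- withr::local_tempfile(lines = c(">t1 some desc", "acgt", "ACGT",
                                        ">t2", "NNAA"))
  rec <- read_fasta(tf)
  expect_equal(rec$id, c("t1", "t2"))
  expect_equal(rec$desc, c("some desc", ""))
  expect_equal(rec$seq, c("ACGTACGT", "NNAA"))
  expect_equal(nchar(rec$seq[1]), 8L)
})

test_that("read_fasta handles empty input and rejects bad records", {
  tf <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_fasta(tf)), 0L)
  dup <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "ACGT"))
  expect_error(read_fasta(dup), "duplicate.*a")
  bad <- withr::local_tempfile(lines = c(">a", "ACG1T"))
  expect_error(read_fasta(bad), "position 4")
  amb <- withr::local_tempfile(lines = c(">a", "ACRT"))
  expect_warning(r <- read_fasta(amb, alphabet = "dna"), "ambiguity")
  expect_equal(r$seq, "ACNT")
  expect_error(read_fasta(amb, alphabet = "any"), NA)
})

test_that("FASTA round trip is the identity on fuzz-generated records", {
  set.seed(101)
  for (i in 1:100) {
    recs <- rand_fasta_records()
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    write_fasta(recs, tf, width = sample(c(10L, 60L, 80L), 1L))
    expect_identical(read_fasta(tf), recs)
  }
})

test_that("write_fasta wraps deterministically", {
  tf <- withr::local_tempfile()
  write_fasta(data.frame(id = "t1", desc = "", seq = "ACGTACGT"), tf)
  expect_equal(readLines(tf), c(">t1", "ACGTACGT"))
  b1 <- readBin(tf, "raw", file.size(tf))
  write_fasta(data.frame(id = "t1", desc = "", seq = "ACGTACGT"), tf)
  expect_identical(readBin(tf, "raw", file.size(tf)), b1)
  write_fasta(data.frame(id = character(), desc = character(),
                         seq = character()), tf)
  expect_equal(file.size(tf), 0)
})

test_that("parse_blast_tab maps the 12 columns and derives strand", {
  tf <- withr::local_tempfile(lines = c(
    "P58608\tTRX_1\t85.2\t54\t8\t0\t1\t54\t10\t171\t2e-25\t110",
    "P58608\tTRX_2\t85.2\t54\t8\t0\t1\t54\t300\t100\t1e-10\t90"))
  h <- parse_blast_tab(tf)
  expect_equal(h$query_id[1], "P58608")
  expect_equal(h$subject_id[1], "TRX_1")
  expect_equal(h$evalue[1], 2e-25)
  expect_equal(h$strand, c("+", "-"))
  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(parse_blast_tab(empty)), 0L)
})

test_that("parse_blast_tab rejects malformed rows with line numbers", {
  tf <- withr::local_tempfile(lines = c(
    "P1\tT1\t85.2\t54\t8\t0\t1\t54\t10\t171\t2e-25\t110",
    "P1\tT1\t85.2\t54"))
  expect_error(parse_blast_tab(tf), "line 2.*12")
  tf2 <- withr::local_tempfile(lines =
    "P1\tT1\tzz\t54\t8\t0\t1\t54\t10\t171\t2e-25\t110")
  expect_error(parse_blast_tab(tf2), "line 1, column 3")
})

test_that("outfmt-6 serialize-then-parse is the identity on fuzz hits", {
  set.seed(102)
  for (i in 1:100) {
    hits <- rand_hit_table(n_hits = sample(1:20, 1))$hits
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    write_blast_tab(hits, tf)
    back <- parse_blast_tab(tf)
    back$strand <- NULL
    hits$strand <- NULL
    rownames(back) <- rownames(hits) <- NULL
    expect_equal(back, hits)
  }
})

test_that("expression tables locate columns by header name", {
  tf <- withr::local_tempfile(lines = c(
    "transcript_id\tlength\texpected_count\tTPM\tFPKM",
    "t1\t500\t12.5\t3.25\t3.10"))
  rec <- parse_expression_table(tf, sample_label = "venom_gland")
  expect_equal(rec$tpm, 3.25)
  expect_equal(rec$fpkm, 3.10)
  expect_equal(rec$sample, "venom_gland")
  rec2 <- parse_expression_table(tf, sample_label = "carcass")
  expect_true(!identical(rec$sample, rec2$sample))
})

test_that("expression tables reject bad TPM and missing columns", {
  neg <- withr::local_tempfile(lines = c("id\tTPM", "t1\t-4"))
  expect_error(parse_expression_table(neg, "s"), ">= 0")
  noc <- withr::local_tempfile(lines = c("id\tabundance", "t1\t4"))
  expect_error(parse_expression_table(noc, "s"), "available headers.*abundance")
})

test_that("signal tables parse flags, comments and cleavage positions", {
  tf <- withr::local_tempfile(lines = c("# header", "prot1\tY\t22\t0.85",
                                        "prot2\tN\t-\t0.10"))
  s <- parse_signal_table(tf)
  expect_equal(s$has_signal, c(TRUE, FALSE))
  expect_equal(s$cleavage_after, c(22L, NA_integer_))
  only_comments <- withr::local_tempfile(lines = c("# a", "# b"))
  expect_equal(nrow(parse_signal_table(only_comments)), 0L)
  bad <- withr::local_tempfile(lines = "prot1\tY\t-\t0.85")
  expect_error(parse_signal_table(bad), "no cleavage")
})

test_that("query metadata requires the four columns and unique accessions", {
  tf <- withr::local_tempfile(lines = c(
    "accession\tprotein_name\torganism\tlineage",
    "P1\tNeprilysin-1\tUrodacus yaschenkoi\tEukaryota;Metazoa"))
  m <- read_query_meta(tf)
  expect_equal(m$protein_name, "Neprilysin-1")
  bad <- withr::local_tempfile(lines = c("accession\tprotein_name",
                                         "P1\tx"))
  expect_error(read_query_meta(bad), "missing column")
})

test_that("UniProt-style headers yield accession, protein name and organism", {
  recs <- data.frame(
    id = c("sp|P58608|TXL14_MESMA", "plainid"),
    desc = c("Toxin-like protein 14 OS=Mesobuthus martensii OX=34649 PE=1",
             "Neprilysin-1"),
    seq = c("MKC", "MKC"), stringsAsFactors = FALSE)
  m <- parse_toxprot_headers(recs)
  expect_equal(m$accession, c("P58608", "plainid"))
  expect_equal(m$protein_name, c("Toxin-like protein 14", "Neprilysin-1"))
  expect_equal(m$organism, c("Mesobuthus martensii", ""))
})

test_that("write_newick emits the canonical three-leaf star", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(neighbor_joining(d))
  expect_equal(txt, "(A:0.500000,B:1.500000,C:2.500000);")
})

test_that("write_newick escapes awkward leaf labels", {
  tr <- toxtriage:::two_leaf_tree(c("Toxin 14", "B"), 1)
  txt <- write_newick(tr)
  expect_match(txt, "Toxin_14", fixed = TRUE)
  p <- ape::read.tree(text = txt)
  expect_setequal(p$tip.label, c("Toxin_14", "B"))
})

test_that("Newick write-parse-write is idempotent on random trees", {
  set.seed(103)
  for (i in 1:100) {
    tr <- ape::rtree(sample(3:15, 1))
    first <- write_newick(tr)
    again <- write_newick(parse_newick(first))
    expect_identical(again, first)
  }
})
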