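test_that("family members share the cysteine skeleton and a qualifying signal", {
  fam <- simulate_family("Skeleton family", 4, seed = 1)
  expect_length(fam$members, 4L)
  cys_pos <- function(p) which(strsplit(p, "")[[1]] == "C")
  mature <- substring(fam$members, fam$signal_len + 1L)
  skeletons <- lapply(mature, cys_pos)
  expect_true(all(vapply(skeletons, identical, logical(1), skeletons[[1]])))
  expect_gte(length(skeletons[[1]]), 6L)
  expect_identical(simulate_family("Skeleton family", 4, seed = 1), fam)
})

test_that("within-family distances fall below between-family distances", {
  set.seed(801)
  ok <- vapply(1:20, function(s) {
    f1 <- simulate_family("Family one", 3, seed = s)
    f2 <- simulate_family("Family two", 3, seed = s + 1000)
    aln <- progressive_msa(c(f1$members, f2$members))
    d <- p_distance(aln)
    in1 <- names(f1$members); in2 <- names(f2$members)
    within <- c(d[in1, in1][upper.tri(diag(3))],
                d[in2, in2][upper.tri(diag(3))])
    between <- as.vector(d[in1, in2])
    max(within) < min(between)
  }, logical(1))
  expect_true(all(ok))
})

test_that("simulated inputs have the promised shape and are seed-deterministic", {
  d1 <- fresh_dir(); d2 <- fresh_dir()
  withr::defer(unlink(c(d1, d2), recursive = TRUE))
  s1 <- simulate_inputs(5, 4, 150, c("venom_gland", "carcass"), seed = 7,
                        outdir = d1)
  expect_equal(nrow(s1$truth), 170L)  # 5*4 toxins + 150 decoys
  expect_equal(nrow(read_transcriptome(s1$paths$transcriptome)), 170L)
  hits <- parse_blast_tab(s1$paths$toxin_hits)
  expect_equal(nrow(hits), 20L)
  expect_setequal(hits$subject_id,
                  s1$truth$transcript_id[s1$truth$class == "toxin"])
  s2 <- simulate_inputs(5, 4, 150, c("venom_gland", "carcass"), seed = 7,
                        outdir = d2)
  expect_same_files(d1, d2)
  expect_error(simulate_inputs(2, 2, 2, "vg", 1, outdir = d1), "not empty")
})

test_that("planted ORFs are recovered with matching coordinates on both strands", {
  d <- fresh_dir(); withr::defer(unlink(d, recursive = TRUE))
  sim <- simulate_inputs(3, 3, 5, "venom_gland", seed = 21, outdir = d)
  tx <- read_transcriptome(sim$paths$transcriptome)
  toxins <- sim$truth[sim$truth$class == "toxin", ]
  expect_true(any(toxins$strand == "-"))
  for (i in seq_len(nrow(toxins))) {
    orfs <- find_orfs(tx$seq[tx$id == toxins$transcript_id[i]], 30,
                      toxins$transcript_id[i])
    hit <- orfs[orfs$start == toxins$orf_start[i] &
                  orfs$end == toxins$orf_end[i] &
                  orfs$strand == toxins$strand[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$completeness, "complete")
  }
})

test_that("emitted files replay into every field of the truth table", {
  d <- fresh_dir(); withr::defer(unlink(d, recursive = TRUE))
  sim <- simulate_inputs(2, 3, 10, c("venom_gland", "carcass"), seed = 33,
                        outdir = d)
  truth <- sim$truth
  # expression files agree with the truth TPM columns
  for (tissue in c("venom_gland", "carcass")) {
    ex <- parse_expression_table(sim$paths$expression[[tissue]], tissue)
    expect_equal(ex$tpm[match(truth$transcript_id, ex$transcript_id)],
                 truth[[paste0("tpm_", tissue)]])
  }
  # group keys match the metadata protein names
  meta <- read_query_meta(sim$paths$query_meta)
  keys <- normalize_group_name(meta$protein_name)
  expect_true(all(truth$group_key[truth$class == "toxin"] %in% keys))
  # signal lengths match the predictor on the planted precursors
  queries <- read_fasta(sim$paths$queries)
  expect_equal(nrow(queries), 2L)
})
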