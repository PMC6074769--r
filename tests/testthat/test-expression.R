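expr_df <- function(ids, samples, tpm, fpkm = NA_real_) {
  data.frame(transcript_id = ids, sample = samples, tpm = tpm, fpkm = fpkm,
             expected_count = NA_real_, stringsAsFactors = FALSE)
}

tx_df <- function(ids) {
  data.frame(id = ids, desc = "", seq = strrep("ACGT", 10),
             stringsAsFactors = FALSE)
}

test_that("the TPM filter is strictly greater-than at the boundary", {
  tx <- tx_df(c("t1", "t2", "t3"))
  ex <- expr_df(c("t1", "t2", "t3"), "vg", c(0.5, 1.0, 1.01))
  expect_equal(tpm_filter(tx, ex, 1.0)$id, "t3")
  expect_equal(tpm_filter(tx, ex, 0)$id, c("t1", "t2", "t3"))
  expect_message(out <- tpm_filter(tx_df(c("t1", "zz")), ex, 1.0),
                 "no expression record")
  expect_equal(out$id, character(0))
})

test_that("multi-sample filtering passes on any sample's TPM", {
  tx <- tx_df("t1")
  ex <- expr_df(c("t1", "t1"), c("vg", "skin"), c(0.2, 5))
  expect_equal(tpm_filter(tx, ex, 1.0)$id, "t1")
})

test_that("filter counts match brute force and are monotone in the cutoff", {
  set.seed(701)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    ids <- sprintf("t%03d", seq_len(n))
    ns <- sample(1:3, 1)
    ex <- do.call(rbind, lapply(seq_len(ns), function(s)
      expr_df(ids, sprintf("s%d", s), round(runif(n, 0, 5), 2))))
    tx <- tx_df(ids)
    cutoff <- runif(1, 0, 4)
    got <- suppressMessages(tpm_filter(tx, ex, cutoff))
    brute <- sum(vapply(ids, function(id)
      max(ex$tpm[ex$transcript_id == id]) > cutoff, logical(1)))
    expect_equal(nrow(got), brute)
    higher <- suppressMessages(tpm_filter(tx, ex, cutoff + 1))
    expect_true(all(higher$id %in% got$id))
  }
})

test_that("group expression tables report every member across samples", {
  g <- structure(list(name = "G", display_name = "G", queries = "Q",
                      members = data.frame(transcript_id = c("t1", "t2", "t3"),
                                           stringsAsFactors = FALSE)),
                 class = "toxin_group")
  ex <- expr_df(c("t1", "t2", "t1", "t2"), rep(c("vg", "skin"), each = 2),
                c(10, 200, 1, 2), fpkm = c(9, 180, 1, 2))
  tab <- group_expression_table(g, ex)
  expect_equal(dim(tab), c(3L, 5L))  # id + 2 tpm + 2 fpkm
  expect_equal(tab$transcript_id, c("t2", "t1", "t3"))  # by max TPM desc
  expect_true(all(is.na(tab[tab$transcript_id == "t3",
                            c("tpm_skin", "tpm_vg")])))
  # column sums match direct aggregation
  expect_equal(sum(tab$tpm_vg, na.rm = TRUE),
               sum(ex$tpm[ex$sample == "vg"]))
})

test_that("tissue reports flag the maximal sample and highlight threshold", {
  ex <- expr_df(c("c1", "c1"), c("venom_gland", "skin"), c(250, 3))
  rep1 <- tissue_report("c1", ex, highlight_tpm = 100)
  expect_equal(rep1$max_sample, "venom_gland")
  expect_true(rep1$highlight)
  expect_false(rep1$tie)
  # all-zero: lexicographically first sample, tie flagged, no highlight
  ex0 <- expr_df(c("c2", "c2"), c("venom_gland", "skin"), c(0, 0))
  rep0 <- tissue_report("c2", ex0, highlight_tpm = 100)
  expect_equal(rep0$max_sample, "skin")
  expect_true(rep0$tie)
  expect_false(rep0$highlight)
})

test_that("highlight counts match brute force and samples are never invented", {
  set.seed(702)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    ids <- sprintf("c%02d", seq_len(n))
    samples <- sprintf("s%d", seq_len(sample(1:4, 1)))
    ex <- do.call(rbind, lapply(samples, function(s)
      expr_df(ids, s, round(runif(n, 0, 300), 1))))
    thr <- runif(1, 10, 200)
    rep <- tissue_report(ids, ex, thr)
    brute <- sum(vapply(ids, function(id)
      max(ex$tpm[ex$transcript_id == id]) > thr, logical(1)))
    expect_equal(sum(rep$highlight), brute)
    expect_true(all(rep$max_sample %in% samples))
  }
})
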