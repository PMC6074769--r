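test_that("group names sanitize to filesystem-safe keys", {
  expect_equal(normalize_group_name("Delta-latroinsectotoxin-Lt1a"),
               "Delta-latroinsectotoxin-Lt1a")
  expect_equal(normalize_group_name("Toxin-like protein 14"),
               "Toxin-like_protein_14")
  expect_equal(normalize_group_name("A/B toxin"), "A_B_toxin")
  expect_error(normalize_group_name(""), "empty")
})

make_meta <- function(acc, name) {
  data.frame(accession = acc, protein_name = name, organism = "org",
             lineage = "lin", stringsAsFactors = FALSE)
}

make_hits <- function(q, s, e, bs = 100) {
  data.frame(query_id = q, subject_id = s, pct_identity = 90, aln_len = 100,
             mismatches = 1, gap_opens = 0, q_start = 1, q_end = 100,
             s_start = 1, s_end = 300, evalue = e, bit_score = bs,
             stringsAsFactors = FALSE)
}

test_that("queries sharing a protein name merge into one group", {
  meta <- make_meta(c("P1", "P2"), c("Neprilysin-1", "Neprilysin-1"))
  hits <- make_hits(c("P1", "P2", "P1"), c("t1", "t2", "t3"),
                    c(1e-30, 1e-12, 1e-9))
  g <- assign_groups(hits, meta, 1e-6)
  expect_length(g, 1L)
  expect_equal(g[[1]]$name, "Neprilysin-1")
  expect_equal(sort(g[[1]]$members$transcript_id), c("t1", "t2", "t3"))
  expect_setequal(g[[1]]$queries, c("P1", "P2"))
})

test_that("a transcript joins every group it hits within the cutoff", {
  meta <- make_meta(c("P1", "P2"), c("Group one", "Group two"))
  hits <- make_hits(c("P1", "P2"), c("T", "T"), c(1e-30, 1e-8))
  g <- assign_groups(hits, meta, 1e-6)
  expect_length(g, 2L)
  expect_true(all(vapply(g, function(x) "T" %in% x$members$transcript_id,
                         logical(1))))
  single <- assign_groups(hits, meta, 1e-6, multi_group = FALSE)
  expect_length(single, 1L)
  expect_equal(single[[1]]$display_name, "Group one")
})

test_that("grouping rejects unknown accessions and empty passes", {
  meta <- make_meta("P1", "X")
  expect_error(assign_groups(make_hits("P9", "t", 1e-30), meta, 1e-6),
               "unknown query.*P9")
  expect_length(assign_groups(make_hits("P1", "t", 1e-3), meta, 1e-6), 0L)
})

test_that("per-(group, transcript) best hits match an exhaustive scan", {
  set.seed(301)
  for (i in 1:20) {
    rt <- rand_hit_table()
    cutoff <- 10^runif(1, -30, -2)
    groups <- assign_groups(rt$hits, rt$meta, cutoff)
    pass <- rt$hits[rt$hits$evalue <= cutoff, ]
    pass$gname <- rt$meta$protein_name[match(pass$query_id,
                                             rt$meta$accession)]
    # every passing hit's subject is in the right group with the true best
    for (g in groups) {
      sub <- pass[pass$gname == g$display_name, ]
      expect_setequal(g$members$transcript_id, unique(sub$subject_id))
      for (r in seq_len(nrow(g$members))) {
        mine <- sub[sub$subject_id == g$members$transcript_id[r], ]
        expect_equal(g$members$evalue[r], min(mine$evalue))
      }
    }
    # conservation: all passing subjects appear in >= 1 group
    covered <- unique(unlist(lapply(groups, function(g)
      g$members$transcript_id)))
    expect_setequal(covered, unique(pass$subject_id))
  }
})

test_that("the reciprocal E-value rule classifies the worked examples", {
  t30 <- make_hits("T", "p", 1e-30)
  n5 <- make_hits("N", "p", 1e-5)
  expect_equal(classify_candidate("p", t30, n5, 0)$verdict, "candidate")
  expect_equal(classify_candidate("p", t30, NULL, 0)$verdict, "candidate")
  expect_equal(classify_candidate("p", make_hits("T", "p", 1e-6), n5,
                                  2)$verdict, "rejected")
  expect_equal(classify_candidate("p", t30[0, ], n5, 0)$verdict,
               "unevaluated")
  # zero E-values are floored, not -Inf
  z <- classify_candidate("p", make_hits("T", "p", 0), n5, 0)
  expect_equal(z$verdict, "candidate")
  expect_true(is.finite(z$margin_orders))
  expect_error(classify_candidate("p", make_hits("T", "p", -1), NULL),
               "negative")
})

test_that("screening verdicts match a brute-force rule evaluation", {
  set.seed(302)
  brute <- function(te, ne, margin) {
    if (length(te) == 0) return("unevaluated")
    if (length(ne) == 0) return("candidate")
    lt <- log10(max(min(te), 1e-200))
    ln <- log10(max(min(ne), 1e-200))
    if (ln - lt >= margin) "candidate" else "rejected"
  }
  for (i in 1:100) {
    nt <- sample(0:5, 1); nn <- sample(0:5, 1)
    te <- 10^runif(nt, -250, 0)
    if (nt > 0 && runif(1) < 0.1) te[1] <- 0
    ne <- 10^runif(nn, -250, 0)
    margin <- sample(c(0, 1, 2.5), 1)
    th <- if (nt > 0) make_hits(sprintf("T%d", seq_len(nt)), "p", te) else
      make_hits("T", "p", 1)[0, ]
    nh <- if (nn > 0) make_hits(sprintf("N%d", seq_len(nn)), "p", ne) else
      NULL
    v <- classify_candidate("p", th, nh, margin)
    expect_equal(v$verdict, brute(te, ne, margin))
    # monotonicity: improving the best toxin E-value never demotes
    if (nt > 0 && v$verdict == "candidate") {
      th2 <- th; th2$evalue <- th2$evalue * 1e-10
      expect_equal(classify_candidate("p", th2, nh, margin)$verdict,
                   "candidate")
    }
  }
})

test_that("the stringency sweep counts thresholds correctly", {
  meta <- make_meta(c("P1", "P2"), c("G1", "G2"))
  hits <- make_hits(c("P1", "P2"), c("t1", "t2"), c(1e-25, 1e-10))
  sw <- stringency_sweep(hits, meta, c(1e-20, 1e-6))
  expect_equal(sw$n_groups, c(1L, 2L))
  expect_equal(sw$n_transcripts, c(1L, 2L))
  empty <- stringency_sweep(hits[0, ], meta, c(1e-20, 1e-6))
  expect_equal(empty$n_groups, c(0L, 0L))
  expect_equal(empty$n_transcripts, c(0L, 0L))
})

test_that("looser cutoffs never shrink groups or transcripts", {
  set.seed(303)
  for (i in 1:30) {
    rt <- rand_hit_table()
    sw <- stringency_sweep(rt$hits, rt$meta, c(1e-40, 1e-20, 1e-10, 1e-2, 1))
    expect_true(all(diff(sw$n_groups) >= 0))
    expect_true(all(diff(sw$n_transcripts) >= 0))
  }
})
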