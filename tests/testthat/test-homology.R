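test_that("tabular hit parsing handles the 12-column dialect", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment",
               "q1\ts1\t100.00\t500\t0\t0\t1\t500\t1\t500\t1e-200\t924",
               "q2\ts2\t85.50\t200\t29\t0\t1\t200\t10\t209\t1e-50\t185"), f)
  tab <- parse_tabular_hits(f)
  expect_s3_class(tab, "hit_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$pct_identity[1], 100)
  expect_equal(tab$evalue[1], 1e-200)
  expect_equal(tab$bitscore[2], 185)

  writeLines(c("# only", "# comments"), f)
  expect_equal(nrow(parse_tabular_hits(f)), 0L)

  writeLines(c("q1\ts1\t100\t500\t0\t0\t1\t500\t1\t500\t1e-200",  # 11 cols
               "q2\ts2\tNOTNUM\t200\t0\t0\t1\t200\t1\t200\t1e-5\t100"), f)
  expect_warning(tab <- parse_tabular_hits(f), "line\\(s\\): 1, 2")
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "rejected_lines"), c(1L, 2L))
})

test_that("hit tables round-trip through write/parse", {
  tabs <- random_hit_tables(11)
  f <- withr::local_tempfile()
  write_tabular_hits(tabs$forward, f)
  back <- parse_tabular_hits(f)
  attr(back, "rejected_lines") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(tabs$forward),
               tolerance = 1e-6)
})

test_that("filter_hits applies inclusive thresholds and is idempotent", {
  tab <- hit_table(data.frame(
    query_id = c("q1", "q2", "q3"), subject_id = c("s1", "s2", "s3"),
    pct_identity = c(69.9, 70.0, 100), aln_length = 100L, mismatches = 0L,
    gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = c(1e-10, 1e-5, 2e-5), bitscore = 100))
  out <- filter_hits(tab, 1e-5, 70)
  expect_equal(out$query_id, "q2")  # 69.9 identity out; 2e-5 evalue out
  expect_equal(as.data.frame(filter_hits(out, 1e-5, 70)),
               as.data.frame(out))
  # thresholds commute
  for (s in 1:5) {
    t2 <- random_hit_tables(s)$forward
    a <- filter_hits(filter_hits(t2, 1e-10, 0), 1, 90)
    b <- filter_hits(filter_hits(t2, 1, 90), 1e-10, 0)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
  expect_equal(nrow(filter_hits(hit_table(NULL), 1e-5, 70)), 0L)
})

test_that("best_hit_per_query maximizes bitscore with documented tie-breaks", {
  mk <- function(q, s, bs, ev = 1e-10, id = 90) data.frame(
    query_id = q, subject_id = s, pct_identity = id, aln_length = 100L,
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 100L,
    s_start = 1L, s_end = 100L, evalue = ev, bitscore = bs)
  tab <- hit_table(rbind(mk("q1", "s2", 180), mk("q1", "s1", 200),
                         mk("q2", "s2", 200), mk("q2", "s1", 200)))
  best <- best_hit_per_query(tab)
  expect_equal(best$subject_id[best$query_id == "q1"], "s1")
  expect_equal(best$subject_id[best$query_id == "q2"], "s1")  # lexicographic
  # tie broken by evalue before subject id
  tab2 <- hit_table(rbind(mk("q1", "s9", 200, ev = 1e-30),
                          mk("q1", "s1", 200, ev = 1e-10)))
  expect_equal(best_hit_per_query(tab2)$subject_id, "s9")
  expect_equal(nrow(best_hit_per_query(hit_table(NULL))), 0L)
  # against the pairwise-comparison oracle on random tables
  for (s in 1:10) {
    tab <- random_hit_tables(s)$forward
    best <- best_hit_per_query(tab)
    for (q in unique(tab$query_id))
      expect_equal(best$subject_id[best$query_id == q],
                   best_subject_oracle(tab, q))
  }
})

test_that("reciprocal_best_hits matches the brute-force oracle", {
  for (s in 1:25) {
    tabs <- random_hit_tables(s)
    got <- reciprocal_best_hits(tabs$forward, tabs$reverse)
    expect_equal(got, rbh_oracle(tabs$forward, tabs$reverse), info = s)
    # injective on both sides
    expect_false(anyDuplicated(got$query_id) > 0)
    expect_false(anyDuplicated(got$subject_id) > 0)
    # symmetric under table swap
    swapped <- reciprocal_best_hits(tabs$reverse, tabs$forward)
    expect_setequal(paste(got$query_id, got$subject_id),
                    paste(swapped$subject_id, swapped$query_id))
  }
})

test_that("naive_search finds identical, reverse-complement and no hits", {
  set.seed(99)
  subj <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
          collapse = ""), character(1))
  names(subj) <- paste0("s", 1:4)

  hits <- naive_search(c(q1 = subj[["s2"]]), subj, k = 11)
  top <- as.data.frame(best_hit_per_query(hits))
  expect_equal(top$subject_id, "s2")
  expect_equal(top$pct_identity, 100)
  expect_equal(top$aln_length, 400L)
  expect_equal(c(top$q_start, top$q_end, top$s_start, top$s_end),
               c(1L, 400L, 1L, 400L))

  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(subj[["s3"]], "")[[1]]), collapse = ""))
  hits2 <- naive_search(c(qrc = rc), subj, k = 11)
  top2 <- as.data.frame(best_hit_per_query(hits2))
  expect_equal(top2$subject_id, "s3")
  expect_equal(top2$pct_identity, 100)
  expect_true(top2$s_start > top2$s_end)  # minus strand convention

  none <- naive_search(c(q0 = paste(rep("A", 100), collapse = "")),
                       c(sT = paste(rep("C", 120), collapse = "")), k = 12)
  expect_equal(nrow(none), 0L)

  expect_error(naive_search(c(q = "ACGTXACGTACG"), subj, k = 8),
               "non-IUPAC")
})

test_that("a query equal to a subject always tops its own hit list", {
  set.seed(7)
  subj <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(300:600, 1),
                 replace = TRUE), collapse = ""), character(1))
  names(subj) <- paste0("s", 1:6)
  for (i in seq_along(subj)) {
    hits <- naive_search(subj[i], subj, k = 11)
    best <- best_hit_per_query(hits)
    expect_equal(best$subject_id, names(subj)[i])
  }
})
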