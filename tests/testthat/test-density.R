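test_that("bin_index implements half-open zero-based bins", {
  expect_equal(bin_index(9500000, 1e6), 9L)
  expect_equal(bin_label(9L, 1e6, "bp"), "9-10 Mb")
  expect_equal(bin_index(0, 1e6), 0L)
  expect_equal(bin_index(1e7, 1e6), 10L)  # boundary opens the next bin
  expect_equal(bin_index(c(0, 5, 10, 19.99), 5), c(0L, 1L, 2L, 3L))
  expect_error(bin_index(-1, 1e6), "non-negative")
  # cM labels in cM units
  expect_equal(bin_label(2L, 5, "cM"), "10-15 cM")
})

test_that("bin grids tile chromosomes", {
  g <- bin_grid(chromosome_def("c", 100), 10, "bp")
  expect_equal(g$n_bins, 10L)
  g2 <- bin_grid(chromosome_def("c", 101), 10, "bp")
  expect_equal(g2$n_bins, 11L)
  expect_length(g2$labels, 11L)
})

test_that("build_density counts all vs tagged genes per bin", {
  idx <- tiny_index()  # 3B: g1@10,g2@50,g3@75; 5A: g4@5,g5@60; width 10
  ts <- query_by_ids(idx, c("g2", "g6"))
  tr <- build_density(idx, ts)
  t3B <- tr[["3B"]]
  expect_equal(sum(t3B$all_counts), 3L)
  expect_equal(t3B$all_counts[c(2, 6, 8)], c(1L, 1L, 1L))
  expect_equal(sum(t3B$tagged_counts), 1L)
  expect_equal(t3B$tagged_counts[6], 1L)   # g2 at 50 -> bin 5
  expect_equal(t3B$relative[6], 1)
  # empty bins flagged, relative 0 not NaN
  expect_true(all(t3B$empty[t3B$all_counts == 0]))
  expect_false(any(is.nan(t3B$relative)))
  # unanchored tagged gene reported separately
  expect_equal(attr(tr, "unanchored_tagged"), 1L)
  # empty tagged set
  tr0 <- build_density(idx, query_by_ids(idx, character()))
  expect_true(all(tr0[["3B"]]$tagged_counts == 0))
  expect_true(all(tr0[["3B"]]$relative == 0))
})

test_that("density conservation: bin sums equal anchored counts", {
  for (s in c(3, 4)) {
    spec <- fixture_spec(seed = s, with_sequences = FALSE)
    idx <- make_genome(spec)
    ts <- query_by_ids(idx, sample(idx$genes$gene_id, 40))
    tr <- build_density(idx, ts)
    for (chrom in names(idx$chromosomes)) {
      n_anch <- sum(idx$genes$anchored &
                      idx$genes$chromosome == chrom, na.rm = TRUE)
      expect_equal(sum(tr[[chrom]]$all_counts), n_anch)
      expect_true(all(tr[[chrom]]$tagged_counts <= tr[[chrom]]$all_counts))
    }
  }
  # saturation: all genes tagged -> relative 1 in every non-empty bin
  spec <- fixture_spec(seed = 6, n_genes = 100L, frac_unanchored = 0,
                       with_sequences = FALSE)
  idx <- make_genome(spec)
  tr <- build_density(idx, query_by_ids(idx, idx$genes$gene_id))
  for (t in tr) expect_true(all(t$relative[!t$empty] == 1))
})

test_that("fisher_one_sided equals the frozen worked examples", {
  # zero tagged on unit: P(X >= 0) = 1 regardless of margins
  expect_equal(fisher_one_sided(0, 5, 3, 7), 1)
  # (5,0,0,5): only the observed table is at least as extreme: 1/C(10,5)
  expect_equal(fisher_one_sided(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  # (3,1,1,3): N=8, K=4, n=4 -> (C(4,3)C(4,1)+C(4,4)C(4,0))/C(8,4) = 17/70
  expect_equal(fisher_one_sided(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_error(fisher_one_sided(0, 0, 0, 0), "all-zero")
  expect_error(fisher_one_sided(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_one_sided is monotone in the on-unit tagged count", {
  # moving one tagged gene onto the unit (margins for tagged total and
  # unit size fixed) never increases p
  for (K in c(5, 10)) for (n in c(6, 12)) {
    N <- 30
    ps <- vapply(max(0, n - (N - K)):min(K, n), function(a) {
      fisher_one_sided(a, K - a, n - a, N - K - n + a)
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("enrich builds correct tables, Bonferroni and ordering", {
  idx <- tiny_index()
  ts <- query_by_ids(idx, c("g1", "g2"))  # both on 3B
  en <- enrich(idx, ts, unit = "chromosome")
  expect_equal(attr(en, "n_units_tested"), 2L)
  # counts sum to anchored genes in every row
  expect_true(all(rowSums(en[, c("tagged_on", "tagged_off", "untagged_on",
                                 "untagged_off")]) == 5))
  r3B <- en[en$unit == "3B", ]
  expect_equal(c(r3B$tagged_on, r3B$tagged_off, r3B$untagged_on,
                 r3B$untagged_off), c(2, 0, 1, 2))
  expect_equal(r3B$p_raw, fisher_oracle(2, 0, 1, 2), tolerance = 1e-12)
  expect_equal(en$p_adj, pmin(1, en$p_raw * 2))
  expect_true(all(en$p_adj >= en$p_raw))
  expect_true(!is.unsorted(en$p_adj))
  # arm units split chromosomes with declared boundaries
  en_arm <- enrich(idx, ts, unit = "arm")
  expect_setequal(en_arm$unit, c("3BS", "3BL", "5A"))
  expect_equal(attr(en_arm, "n_units_tested"), 3L)
  # all genes tagged -> no contrast, p_raw = 1 everywhere
  en_all <- enrich(idx, query_by_ids(idx, paste0("g", 1:5)), "chromosome")
  expect_true(all(en_all$p_raw == 1))
  expect_error(enrich(idx, query_by_ids(idx, character())), "empty")
})

test_that("planted arm enrichment is recovered on a single fixture", {
  spec <- fixture_spec(seed = 77, n_chromosomes = 3L, n_genes = 500L,
                       with_sequences = FALSE,
                       planted_enriched_unit = list(unit = "chr1S",
                                                    n_extra_tagged = 20L))
  fx <- make_enrichment_fixture(spec)
  en <- enrich(fx$index, fx$tagged, unit = "arm")
  expect_equal(en$unit[1], "chr1S")
  expect_lt(en$p_adj[1], 0.05)
  # oracle agreement on the top row
  expect_equal(en$p_raw[1],
               fisher_oracle(en$tagged_on[1], en$tagged_off[1],
                             en$untagged_on[1], en$untagged_off[1]),
               tolerance = 1e-10)
})

test_that("density and enrichment TSVs round-trip", {
  idx <- tiny_index()
  ts <- query_by_ids(idx, c("g1", "g2"))
  tr <- build_density(idx, ts)
  f <- withr::local_tempfile()
  write_density_tsv(tr, f)
  df <- read_density_tsv(f)
  expect_equal(nrow(df), sum(vapply(tr, function(t) t$grid$n_bins,
                                    integer(1))))
  d3B <- df[df$chromosome == "3B", ]
  expect_equal(d3B$all_count, tr[["3B"]]$all_counts)
  expect_equal(d3B$tagged_count, tr[["3B"]]$tagged_counts)
  expect_equal(d3B$relative, tr[["3B"]]$relative)
  expect_equal(d3B$empty_flag, tr[["3B"]]$empty)
  expect_equal(d3B$bin_label, tr[["3B"]]$grid$labels)

  en <- enrich(idx, ts, "arm")
  write_enrichment_tsv(en, f)
  back <- read_enrichment_tsv(f)
  expect_equal(back$unit, en$unit)
  expect_equal(back$p_raw, en$p_raw, tolerance = 1e-12)
  expect_equal(back$p_adj, en$p_adj, tolerance = 1e-12)
  expect_equal(attr(back, "n_units_tested"), attr(en, "n_units_tested"))
})
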