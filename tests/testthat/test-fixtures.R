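test_that("fixture generation is seed-deterministic and validates specs", {
  spec <- fixture_spec(seed = 1, n_genes = 50L, with_sequences = TRUE,
                       seq_length_range = c(100L, 300L),
                       planted_ortholog_pairs = 0L)
  a <- make_genome(spec)
  b <- make_genome(spec)
  expect_identical(a, b)
  expect_error(fixture_spec(), "seed")
  expect_error(fixture_spec(seed = 1, n_genes = 5L,
                            planted_cluster = list(chromosome = "chr1",
                                                   bin = 0, n = 10L)),
               "planted")
})

test_that("make_genome honors anchoring fraction and planted clusters", {
  spec0 <- fixture_spec(seed = 2, n_genes = 80L, frac_unanchored = 0,
                        with_sequences = FALSE)
  expect_true(all(make_genome(spec0)$genes$anchored))

  spec <- fixture_spec(seed = 3, n_genes = 120L, with_sequences = FALSE,
                       planted_cluster = list(chromosome = "chr2",
                                              bin = 4L, n = 20L))
  idx <- make_genome(spec)
  tr <- build_density(idx, query_by_ids(idx, character()))
  expect_gte(tr[["chr2"]]$all_counts[5], 20L)
  # production validators accept the output
  expect_s3_class(idx, "genome_index")
})

test_that("fixture directories parse cleanly through production readers", {
  spec <- fixture_spec(seed = 4, n_genes = 40L,
                       seq_length_range = c(100L, 200L),
                       planted_ortholog_pairs = 6L,
                       planted_decoy_paralogs = 3L)
  d <- withr::local_tempdir()
  write_fixture_dir(spec, d)
  idx <- load_genome(file.path(d, "config.json"))
  expect_equal(nrow(idx$genes), 40L)
  expect_length(idx$sequences, 40L)
  expect_gt(length(idx$terms), 0L)
  fwd <- parse_tabular_hits(file.path(d, "hits_fwd.tsv"))
  rev <- parse_tabular_hits(file.path(d, "hits_rev.tsv"))
  expect_gt(nrow(fwd), 0L)
  ex <- validate_upload(file.path(d, "expression.tsv"), "expression", idx)
  expect_equal(nrow(ex$object), 40L)
  deg <- validate_upload(file.path(d, "deg.txt"), "deg", idx)
  expect_gt(length(deg$object$gene_ids), 0L)
  gm <- validate_upload(file.path(d, "groups.tsv"), "groups", idx)
  expect_length(gm$object$mapping, 40L)

  # byte-identical on re-generation with the same spec
  d2 <- withr::local_tempdir()
  write_fixture_dir(spec, d2)
  for (fn in list.files(d))
    expect_identical(unname(tools::md5sum(file.path(d, fn))),
                     unname(tools::md5sum(file.path(d2, fn))),
                     info = fn)
})

test_that("planted ortholog pairs are exactly recovered by BBH", {
  spec <- fixture_spec(seed = 8, n_genes = 60L, with_sequences = FALSE,
                       planted_ortholog_pairs = 10L,
                       planted_decoy_paralogs = 5L)
  A <- make_genome(spec, genome_id = "gA")
  B <- make_genome(spec, genome_id = "gB", seed_offset = 100L)
  ht <- make_ortholog_hit_tables(A, B, spec)
  got <- reciprocal_best_hits(ht$forward, ht$reverse)
  expect_equal(got, ht$pairs)
  # and equals the exhaustive oracle
  expect_equal(got, rbh_oracle(ht$forward, ht$reverse))
  # decoys present but strictly lower scoring
  expect_gt(nrow(ht$forward), 10L)
  # identity targets respected within the configured range
  expect_true(all(ht$forward$pct_identity >= 69.9))

  # no pairs -> empty BBH set
  spec0 <- fixture_spec(seed = 9, n_genes = 30L, with_sequences = FALSE,
                        planted_ortholog_pairs = 0L,
                        planted_decoy_paralogs = 0L)
  A0 <- make_genome(spec0, "gA")
  B0 <- make_genome(spec0, "gB", seed_offset = 100L)
  ht0 <- make_ortholog_hit_tables(A0, B0, spec0)
  expect_equal(nrow(reciprocal_best_hits(ht0$forward, ht0$reverse)), 0L)
})

test_that("identity-100 planted pairs survive a strict identity filter", {
  spec <- fixture_spec(seed = 10, n_genes = 40L, with_sequences = FALSE,
                       planted_ortholog_pairs = 5L,
                       planted_decoy_paralogs = 4L,
                       ortholog_identity_range = c(100, 100))
  A <- make_genome(spec, "gA"); B <- make_genome(spec, "gB", 100L)
  ht <- make_ortholog_hit_tables(A, B, spec)
  kept <- filter_hits(ht$forward, 1e-5, 100)
  expect_setequal(paste(kept$query_id, kept$subject_id),
                  paste(ht$pairs$query_id, ht$pairs$subject_id))
})

test_that("synthetic expression exposes constant and high-CV populations", {
  spec <- fixture_spec(seed = 12, n_genes = 100L, with_sequences = FALSE,
                       expression = list(fraction_constant = 1))
  idx <- make_genome(spec)
  ex <- make_expression(spec, idx)
  cvs <- apply(unclass(ex$matrix), 1, cv)
  expect_true(all(cvs == 0, na.rm = TRUE))  # every gene constant

  spec2 <- fixture_spec(seed = 13, n_genes = 200L, with_sequences = FALSE)
  idx2 <- make_genome(spec2)
  ex2 <- make_expression(spec2, idx2)
  cvs2 <- apply(unclass(ex2$matrix), 1, cv)
  expect_equal(ex2$deg$gene_ids, ex2$high_cv_genes)
  expect_gt(median(cvs2[ex2$high_cv_genes], na.rm = TRUE),
            median(cvs2[setdiff(names(cvs2), ex2$high_cv_genes)],
                   na.rm = TRUE))
})

test_that("module group coincides with the planted enriched unit", {
  spec <- fixture_spec(seed = 14, n_chromosomes = 2L, n_genes = 200L,
                       with_sequences = FALSE,
                       planted_enriched_unit = list(unit = "chr1S",
                                                    n_extra_tagged = 15L))
  fx <- make_enrichment_fixture(spec)
  ex <- make_expression(spec, fx$index)
  arms <- gene_arms(fx$index)
  module <- names(ex$groups$mapping)[ex$groups$mapping == "module1"]
  expect_setequal(module, names(arms)[arms == "chr1S"])
  # the planted module ranks its unit first in arm enrichment
  en <- enrich(fx$index, fx$tagged, "arm")
  expect_equal(en$unit[1], "chr1S")
})
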