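# In-code fixtures and independent oracles shared across the suite.

# small deterministic genome: 2 chromosomes (one with arms), 6 genes
# (5 anchored, 1 unanchored), bin width 10
tiny_index <- function() {
  chroms <- list(chromosome_def("3B", 100, arm_boundary = 50),
                 chromosome_def("5A", 80))
  genes <- data.frame(
    gene_id = paste0("g", 1:6),
    chromosome = c("3B", "3B", "3B", "5A", "5A", NA),
    position = c(10, 50, 75, 5, 60, NA),
    anchored = c(rep(TRUE, 5), FALSE),
    stringsAsFactors = FALSE)
  genome_index("tiny", "bp", 10, chroms, genes,
               terms = list(g1 = c("GO:0043565", "PF00001"),
                            g2 = "GO:0043565", g6 = "GO:0043565"),
               sequences = c(g1 = "ACGTACGTACGT", g2 = "TTTTGGGGCCCC",
                             g3 = "AAAACCCCGGGG", g4 = "ACACACACACAC",
                             g5 = "GTGTGTGTGTGT", g6 = "CCCCCCCCAAAA"))
}

write_tiny_anchor_tsv <- function(path,
                                  rows = c("g1\t3B\tS\t11\ttrue",
                                           "g2\t3B\tL\t51\ttrue",
                                           "g3\t\t\t\tfalse")) {
  writeLines(c("gene_id\tchromosome\tarm\tposition\tanchored", rows), path)
  path
}

tiny_config <- function(bin_width = 10) {
  list(genome_id = "tiny", unit = "bp", bin_width = bin_width,
       chromosomes = list(chromosome_def("3B", 100, 50),
                          chromosome_def("5A", 80)))
}

# --- independent oracles ---------------------------------------------------

# hypergeometric upper tail by explicit table enumeration over lchoose
fisher_oracle <- function(a, b, c_, d) {
  N <- a + b + c_ + d; K <- a + b; n <- a + c_
  xs <- max(0, n - (N - K)):min(K, n)
  xs <- xs[xs >= a]
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# best subject of one query by pairwise comparison under the documented
# tie-break (bitscore, evalue, identity, subject id) — no sorting involved
best_subject_oracle <- function(tab, q) {
  rows <- as.data.frame(tab)[tab$query_id == q, , drop = FALSE]
  if (!nrow(rows)) return(NA_character_)
  b <- rows[1, ]
  for (i in seq_len(nrow(rows))[-1]) {
    r <- rows[i, ]
    better <- r$bitscore > b$bitscore ||
      (r$bitscore == b$bitscore && (r$evalue < b$evalue ||
        (r$evalue == b$evalue && (r$pct_identity > b$pct_identity ||
          (r$pct_identity == b$pct_identity &&
             r$subject_id < b$subject_id)))))
    if (better) b <- r
  }
  b$subject_id
}

# exhaustive reciprocal check over all (a, b) pairs; the per-query best is
# computed once per id by the pairwise-comparison oracle above
rbh_oracle <- function(fwd, rev) {
  as_ <- unique(fwd$query_id); bs <- unique(rev$query_id)
  bf <- vapply(as_, function(q) best_subject_oracle(fwd, q), character(1))
  br <- vapply(bs, function(q) best_subject_oracle(rev, q), character(1))
  keep <- list()
  for (a in as_) for (b in bs) {
    if (identical(unname(bf[a]), b) && identical(unname(br[b]), a))
      keep[[length(keep) + 1L]] <- data.frame(query_id = a, subject_id = b,
                                              stringsAsFactors = FALSE)
  }
  out <- if (length(keep)) do.call(rbind, keep)
         else data.frame(query_id = character(), subject_id = character(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random hit-table pair with deliberate score ties
random_hit_tables <- function(seed, n_q = 8, n_s = 8) {
  set.seed(seed)
  gen <- function(qs, ss, direction) {
    rows <- expand.grid(query_id = qs, subject_id = ss,
                        stringsAsFactors = FALSE)
    rows <- rows[runif(nrow(rows)) < 0.4, , drop = FALSE]
    n <- nrow(rows)
    if (!n) return(hit_table(NULL, direction))
    rows$pct_identity <- sample(seq(80, 100, by = 5), n, replace = TRUE)
    rows$aln_length <- sample(100:500, n, replace = TRUE)
    rows$mismatches <- 0L; rows$gap_opens <- 0L
    rows$q_start <- 1L; rows$q_end <- rows$aln_length
    rows$s_start <- 1L; rows$s_end <- rows$aln_length
    rows$evalue <- sample(c(1e-20, 1e-10, 1e-5), n, replace = TRUE)
    rows$bitscore <- sample(50:55, n, replace = TRUE)
    hit_table(rows, direction)
  }
  qs <- paste0("a", seq_len(n_q)); ss <- paste0("b", seq_len(n_s))
  list(forward = gen(qs, ss, "forward"), reverse = gen(ss, qs, "reverse"))
}
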