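# Seeded synthetic-data generator. Every other module is testable against
# these fixtures with no download: genomes with anchored/unanchored genes,
# random nucleotide sequences, annotation terms, planted ortholog pairs
# with decoy paralogs, planted enrichment signals, and expression uploads.
#
# RNG discipline: one base seed per fixture; each sub-generator consumes
# its own derived stream (seed + fixed offset, documented below), so
# adding a field to one sub-generator never reshuffles the others.
#   +1 gene positions / anchoring     +4 expression values
#   +2 nucleotide sequences           +5 ortholog/decoy hit synthesis
#   +3 annotation terms               +6 tag selection (planted signals)

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Specification of a synthetic fixture
#'
#' Defaults describe a small desk-scale genome in the 1 Mb binning regime:
#' 2 chromosomes of 20 Mb, 200 genes placed uniformly, 10% of genes left
#' genetically unanchored, arm boundaries at the chromosome midpoints,
#' random nucleotide gene sequences of 300-3000 bases, and a small GO/PFAM
#' style term vocabulary.
#'
#' @param seed Integer seed; the same spec is byte-identical across runs.
#' @param genome_id Genome identifier.
#' @param n_chromosomes,chromosome_length,unit,bin_width Genome geometry.
#' @param n_genes Total genes (anchored + unanchored).
#' @param frac_unanchored Fraction of genes without a position.
#' @param arm_boundary_frac Arm boundary as a fraction of chromosome
#'   length; `NA` declares chromosomes without arms.
#' @param with_sequences Generate nucleotide sequences? (Disable for
#'   position-only simulations.)
#' @param seq_length_range Min/max sequence length.
#' @param annotate_fraction Fraction of genes receiving 1-3 terms.
#' @param planted_cluster Optional `list(chromosome=, bin=, n=)` placing
#'   `n` extra genes inside one bin.
#' @param planted_enriched_unit Optional `list(unit=, n_extra_tagged=)`
#'   used by [make_enrichment_fixture()].
#' @param n_background_tagged Background tagged genes drawn genome-wide in
#'   enrichment fixtures.
#' @param planted_ortholog_pairs,planted_decoy_paralogs Counts for
#'   [make_ortholog_hit_tables()].
#' @param ortholog_identity_range Target identity range for planted pairs.
#' @param expression List: `n_conditions`, `meanlog`, `sdlog` (log-normal
#'   expression), `fraction_constant` (genes with zero variance),
#'   `fraction_high_cv` (planted variable/DEG genes).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         genome_id = "simA",
                         n_chromosomes = 2L,
                         chromosome_length = 2e7,
                         unit = "bp",
                         bin_width = 1e6,
                         n_genes = 200L,
                         frac_unanchored = 0.1,
                         arm_boundary_frac = 0.5,
                         with_sequences = TRUE,
                         seq_length_range = c(300L, 3000L),
                         annotate_fraction = 0.6,
                         planted_cluster = NULL,
                         planted_enriched_unit = NULL,
                         n_background_tagged = 25L,
                         planted_ortholog_pairs = 10L,
                         planted_decoy_paralogs = 5L,
                         ortholog_identity_range = c(70, 100),
                         expression = list(n_conditions = 6L, meanlog = 3,
                                           sdlog = 1,
                                           fraction_constant = 0.2,
                                           fraction_high_cv = 0.1)) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("fixture_spec requires an integer seed", call. = FALSE)
  n_planted <- (if (is.null(planted_cluster)) 0L else planted_cluster$n) +
    (if (is.null(planted_enriched_unit)) 0L
     else planted_enriched_unit$n_extra_tagged)
  if (n_genes < n_planted)
    stop("n_genes smaller than planted counts", call. = FALSE)
  defaults <- list(n_conditions = 6L, meanlog = 3, sdlog = 1,
                   fraction_constant = 0.2, fraction_high_cv = 0.1)
  expression <- utils::modifyList(defaults, expression)
  structure(list(seed = as.integer(seed), genome_id = genome_id,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = chromosome_length, unit = unit,
                 bin_width = bin_width, n_genes = as.integer(n_genes),
                 frac_unanchored = frac_unanchored,
                 arm_boundary_frac = arm_boundary_frac,
                 with_sequences = with_sequences,
                 seq_length_range = as.integer(seq_length_range),
                 annotate_fraction = annotate_fraction,
                 planted_cluster = planted_cluster,
                 planted_enriched_unit = planted_enriched_unit,
                 n_background_tagged = as.integer(n_background_tagged),
                 planted_ortholog_pairs = as.integer(planted_ortholog_pairs),
                 planted_decoy_paralogs = as.integer(planted_decoy_paralogs),
                 ortholog_identity_range = ortholog_identity_range,
                 expression = expression),
            class = "fixture_spec")
}

.term_vocab <- c(sprintf("GO:%07d", c(43565, 3700, 6355, 16020, 5524,
                                      46872, 8270, 55114)),
                 sprintf("PF%05d", c(1, 67, 296, 560)))

#' Generate a synthetic genome
#'
#' Gene positions are uniform per chromosome (plus an optional planted
#' cluster confined to one bin); a configurable fraction of genes is left
#' genetically unanchored; sequences are i.i.d. uniform nucleotides (no
#' codon structure — sufficient for identity/BBH logic, not biological
#' realism); annotation terms come from a small fixed GO/PFAM-style
#' vocabulary.
#'
#' @param spec A [fixture_spec()].
#' @param genome_id Override of `spec$genome_id` (for building genome
#'   pairs from one spec).
#' @param seed_offset Extra offset added to every sub-stream seed, so two
#'   genomes from one spec differ.
#' @return A [genome_index()] with terms and (optionally) sequences.
#' @export
make_genome <- function(spec, genome_id = spec$genome_id, seed_offset = 0L) {
  stopifnot(inherits(spec, "fixture_spec"))
  base <- spec$seed + seed_offset
  L <- spec$chromosome_length
  chroms <- lapply(seq_len(spec$n_chromosomes), function(i) {
    chromosome_def(paste0("chr", i), L,
                   if (is.na(spec$arm_boundary_frac)) NA_real_
                   else spec$arm_boundary_frac * L)
  })
  n <- spec$n_genes
  ids <- sprintf("%s_g%04d", genome_id, seq_len(n))

  genes <- .with_seed(base + 1L, {
    n_un <- round(spec$frac_unanchored * n)
    unanchored <- if (n_un > 0) sample(n, n_un) else integer()
    chr <- sample(paste0("chr", seq_len(spec$n_chromosomes)), n,
                  replace = TRUE)
    pos <- if (spec$unit == "bp") {
      as.numeric(sample.int(as.integer(L), n, replace = TRUE) - 1L)
    } else {
      stats::runif(n, 0, L)
    }
    if (!is.null(spec$planted_cluster)) {
      pc <- spec$planted_cluster
      take <- setdiff(seq_len(n), unanchored)[seq_len(pc$n)]
      chr[take] <- pc$chromosome
      lo <- pc$bin * spec$bin_width
      pos[take] <- if (spec$unit == "bp") {
        as.numeric(lo + sample.int(as.integer(spec$bin_width), pc$n,
                                   replace = TRUE) - 1L)
      } else stats::runif(pc$n, lo, lo + spec$bin_width)
    }
    chr[unanchored] <- NA_character_
    pos[unanchored] <- NA_real_
    data.frame(gene_id = ids, chromosome = chr, position = pos,
               anchored = !(seq_len(n) %in% unanchored),
               stringsAsFactors = FALSE)
  })

  sequences <- character()
  if (spec$with_sequences) {
    sequences <- .with_seed(base + 2L, {
      lens <- sample(spec$seq_length_range[1]:spec$seq_length_range[2], n,
                     replace = TRUE)
      vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = "")
      }, character(1))
    })
    names(sequences) <- ids
  }

  terms <- .with_seed(base + 3L, {
    n_ann <- round(spec$annotate_fraction * n)
    carriers <- if (n_ann > 0) sort(sample(n, n_ann)) else integer()
    tt <- lapply(carriers, function(i) {
      sample(.term_vocab, sample(1:3, 1))
    })
    stats::setNames(tt, ids[carriers])
  })

  genome_index(genome_id, spec$unit, spec$bin_width, chroms, genes,
               terms = terms, sequences = sequences)
}

# point mutations toward a target percent identity
.mutate_seq <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  flip <- stats::runif(length(chars)) > identity / 100
  if (any(flip)) {
    chars[flip] <- vapply(chars[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate reciprocal hit tables with planted orthologs and decoys
#'
#' Plants 1:1 ortholog pairs between two synthetic genomes: the partner in
#' genome B receives a mutated copy of the genome-A sequence (target
#' identity drawn from `spec$ortholog_identity_range`) and the pair gets
#' top-scoring reciprocal hits in both tables. Decoy paralogs receive
#' strictly lower-scoring extra hits in both directions, so best
#' bidirectional filtering must reject them. Ground truth is returned
#' alongside the tables.
#'
#' @param genomeA,genomeB [genome_index()] objects from [make_genome()].
#' @param spec The [fixture_spec()].
#' @return List with `forward`/`reverse` [hit_table()]s, `pairs` (ground
#'   truth data frame `query_id`, `subject_id`), and updated `genomeB`
#'   (mutated partner sequences).
#' @export
make_ortholog_hit_tables <- function(genomeA, genomeB, spec) {
  P <- spec$planted_ortholog_pairs
  D <- spec$planted_decoy_paralogs
  idsA <- genomeA$genes$gene_id
  idsB <- genomeB$genes$gene_id
  stopifnot(P <= length(idsA), P <= length(idsB))
  .with_seed(spec$seed + 5L, {
    qa <- sample(idsA, P)
    sb <- sample(idsB, P)
    ident <- stats::runif(P, spec$ortholog_identity_range[1],
                          spec$ortholog_identity_range[2])
    if (length(genomeA$sequences) && length(genomeB$sequences)) {
      for (i in seq_len(P))
        genomeB$sequences[[sb[i]]] <- .mutate_seq(genomeA$sequences[[qa[i]]],
                                                  ident[i])
    }
    lens <- if (length(genomeA$sequences))
      nchar(genomeA$sequences[qa]) else rep(1000L, P)
    score <- round(lens * ident / 100)
    mk <- function(q, s, id, len, sc) data.frame(
      query_id = q, subject_id = s, pct_identity = round(id, 2),
      aln_length = as.integer(len),
      mismatches = as.integer(round(len * (1 - id / 100))),
      gap_opens = 0L, q_start = 1L, q_end = as.integer(len), s_start = 1L,
      s_end = as.integer(len), evalue = 2^(-pmin(sc, 1000)) * 1e6,
      bitscore = sc, stringsAsFactors = FALSE)
    fwd <- if (P > 0) mk(qa, sb, ident, lens, score) else NULL
    rev <- if (P > 0) mk(sb, qa, ident, lens, score) else NULL
    if (D > 0 && P > 0) {
      pick <- sample(P, D, replace = TRUE)
      decoyB <- vapply(pick, function(i) sample(setdiff(idsB, sb[i]), 1),
                       character(1))
      decoyA <- vapply(pick, function(i) sample(setdiff(idsA, qa[i]), 1),
                       character(1))
      dident <- pmax(70, ident[pick] - stats::runif(D, 1, 10))
      dscore <- round(score[pick] * stats::runif(D, 0.5, 0.9))
      fwd <- rbind(fwd, mk(qa[pick], decoyB, dident, lens[pick], dscore))
      rev <- rbind(rev, mk(sb[pick], decoyA, dident, lens[pick], dscore))
    }
    pairs <- data.frame(query_id = qa, subject_id = sb,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$query_id), , drop = FALSE]
    rownames(pairs) <- NULL
    list(forward = hit_table(fwd, "forward"),
         reverse = hit_table(rev, "reverse"),
         pairs = pairs, genomeB = genomeB)
  })
}

#' Generate synthetic expression uploads
#'
#' Log-normal expression values for every gene of the genome. A
#' `fraction_constant` of genes is flat across conditions (CV = 0); a
#' disjoint `fraction_high_cv` subset gets strongly inflated
#' between-condition variance and doubles as the differential-expression
#' list. Group labels are random, except that when the spec plants an
#' enriched unit, the genes on that unit form their own `"module1"` group
#' (emulating a co-expression module linked to a QTL region).
#'
#' @param spec A [fixture_spec()].
#' @param index The [genome_index()] the uploads describe.
#' @return List with `matrix` ([expression_matrix()]), `deg` (`deg_list`),
#'   `groups` (`group_map`), and `high_cv_genes`.
#' @export
make_expression <- function(spec, index) {
  ex <- spec$expression
  ids <- index$genes$gene_id
  n <- length(ids)
  .with_seed(spec$seed + 4L, {
    vals <- matrix(stats::rlnorm(n * ex$n_conditions, ex$meanlog, ex$sdlog),
                   nrow = n)
    n_const <- round(ex$fraction_constant * n)
    n_hv <- min(round(ex$fraction_high_cv * n), n - n_const)
    idx <- sample(n)
    const_i <- idx[seq_len(n_const)]
    hv_i <- idx[n_const + seq_len(n_hv)]
    if (n_const > 0)
      vals[const_i, ] <- matrix(rep(stats::rlnorm(n_const, ex$meanlog,
                                                  ex$sdlog),
                                    ex$n_conditions), nrow = n_const)
    if (n_hv > 0)
      vals[hv_i, ] <- vals[hv_i, , drop = FALSE] *
        matrix(exp(stats::rnorm(n_hv * ex$n_conditions, 0, 2)),
               nrow = n_hv)
    rownames(vals) <- ids
    colnames(vals) <- paste0("cond", seq_len(ex$n_conditions))

    groups <- sample(paste0("group", 1:3), n, replace = TRUE)
    names(groups) <- ids
    if (!is.null(spec$planted_enriched_unit)) {
      arms <- gene_arms(index)
      on_unit <- names(arms)[arms == spec$planted_enriched_unit$unit]
      groups[on_unit] <- "module1"
    }
    list(matrix = expression_matrix(vals),
         deg = structure(list(gene_ids = sort(ids[hv_i])),
                         class = "deg_list"),
         groups = structure(list(mapping = groups), class = "group_map"),
         high_cv_genes = sort(ids[hv_i]))
  })
}

#' Build a planted-enrichment fixture
#'
#' Generates the genome of `spec` and a tagged set consisting of
#' `n_background_tagged` anchored genes drawn genome-wide plus
#' `n_extra_tagged` extra tagged genes drawn from the planted unit, the
#' synthetic analogue of a study where candidate genes concentrate on one
#' chromosome arm.
#'
#' @param spec A [fixture_spec()] with `planted_enriched_unit` set.
#' @return List with `index`, `tagged` ([tagged_set()]) and
#'   `planted_unit`.
#' @export
make_enrichment_fixture <- function(spec) {
  stopifnot(!is.null(spec$planted_enriched_unit))
  index <- make_genome(spec)
  pu <- spec$planted_enriched_unit
  arms <- gene_arms(index)
  units <- unique(unname(arms))
  if (!pu$unit %in% units)
    stop("planted unit '", pu$unit, "' not among arm units: ",
         paste(units, collapse = ", "), call. = FALSE)
  on_unit <- names(arms)[arms == pu$unit]
  if (length(on_unit) < pu$n_extra_tagged)
    stop("not enough genes on planted unit", call. = FALSE)
  ids <- .with_seed(spec$seed + 6L, {
    background <- sample(names(arms), min(spec$n_background_tagged,
                                          length(arms)))
    extra <- sample(on_unit, pu$n_extra_tagged)
    union(background, extra)
  })
  tagged <- tagged_set(index$genome_id, ids,
                       provenance = list(mode = "fixture",
                                         planted_unit = pu$unit))
  list(index = index, tagged = tagged, planted_unit = pu$unit)
}

#' Write annotation terms of a genome to TSV
#' @param index A [genome_index()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(index, path) {
  rows <- unlist(lapply(names(index$terms), function(g) {
    paste(g, sort(index$terms[[g]]), sep = "\t")
  }))
  writeLines(c("gene_id\tterm", rows), path)
  invisible(path)
}

#' Write a complete fixture directory
#'
#' Materializes a [fixture_spec()] as plain-text files in the formats the
#' production readers consume: `config.json`, `anchors.tsv`,
#' `genes.fasta`, `annotations.tsv`, `expression.tsv`, `deg.txt`,
#' `groups.tsv`, and — when ortholog pairs are planted — a second genome
#' (`*_B`) plus `hits_fwd.tsv` / `hits_rev.tsv`. Identical specs produce
#' byte-identical directories.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- make_genome(spec)
  cfg <- list(genome_id = index$genome_id, unit = index$unit,
              bin_width = index$bin_width,
              chromosomes = index$chromosomes,
              files = c(list(anchors = "anchors.tsv",
                             annotations = "annotations.tsv"),
                        if (length(index$sequences))
                          list(fasta = "genes.fasta")))
  write_genome_config(cfg, file.path(dir, "config.json"))
  write_anchor_table(index, file.path(dir, "anchors.tsv"))
  if (length(index$sequences))
    write_fasta(index$sequences, file.path(dir, "genes.fasta"))
  write_annotations(index, file.path(dir, "annotations.tsv"))

  expr <- make_expression(spec, index)
  write_expression_tsv(expr$matrix, file.path(dir, "expression.tsv"))
  writeLines(expr$deg$gene_ids, file.path(dir, "deg.txt"))
  utils::write.table(
    data.frame(gene_id = names(expr$groups$mapping),
               group = unname(expr$groups$mapping)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  if (spec$planted_ortholog_pairs > 0) {
    genomeB <- make_genome(spec, genome_id = paste0(spec$genome_id, "_B"),
                           seed_offset = 100L)
    ht <- make_ortholog_hit_tables(index, genomeB, spec)
    cfgB <- list(genome_id = ht$genomeB$genome_id, unit = ht$genomeB$unit,
                 bin_width = ht$genomeB$bin_width,
                 chromosomes = ht$genomeB$chromosomes,
                 files = c(list(anchors = "anchors_B.tsv"),
                           if (length(ht$genomeB$sequences))
                             list(fasta = "genes_B.fasta")))
    write_genome_config(cfgB, file.path(dir, "config_B.json"))
    write_anchor_table(ht$genomeB, file.path(dir, "anchors_B.tsv"))
    if (length(ht$genomeB$sequences))
      write_fasta(ht$genomeB$sequences, file.path(dir, "genes_B.fasta"))
    write_tabular_hits(ht$forward, file.path(dir, "hits_fwd.tsv"))
    write_tabular_hits(ht$reverse, file.path(dir, "hits_rev.tsv"))
    utils::write.table(ht$pairs, file.path(dir, "planted_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
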