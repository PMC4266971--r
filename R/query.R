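#' Construct a tagged gene set
#'
#' A tagged set is the outcome of one query: the ids of the matching genes
#' of one genome, plus a provenance record (query mode, parameters, misses)
#' from which the query can be reconstructed.
#'
#' @param genome_id Genome the set belongs to.
#' @param gene_ids Character vector of gene ids (deduplicated, sorted).
#' @param provenance List describing the query.
#' @return An object of class `tagged_set`.
#' @export
tagged_set <- function(genome_id, gene_ids, provenance = list()) {
  structure(list(genome_id = genome_id,
                 gene_ids = sort(unique(as.character(gene_ids))),
                 provenance = provenance),
            class = "tagged_set")
}

#' @export
print.tagged_set <- function(x, ...) {
  cat("tagged_set (", x$genome_id, "): ", length(x$gene_ids), " genes; mode=",
      if (is.null(x$provenance$mode)) "?" else x$provenance$mode, "\n",
      sep = "")
  invisible(x)
}

.check_genome <- function(index, ids) {
  known <- ids %in% index$genes$gene_id
  list(hit = ids[known], miss = ids[!known])
}

#' Tag genes by identifier list
#'
#' Intersects the supplied ids with the genome. Unknown ids are recorded in
#' the provenance as misses, not errors.
#'
#' @param index A [genome_index()].
#' @param ids Character vector of gene identifiers.
#' @return A [tagged_set()].
#' @export
query_by_ids <- function(index, ids) {
  res <- .check_genome(index, unique(as.character(ids)))
  tagged_set(index$genome_id, res$hit,
             provenance = list(mode = "ids", n_requested = length(unique(ids)),
                               misses = res$miss))
}

#' Tag genes by annotation term
#'
#' Returns all genes — anchored and unanchored — whose term set contains
#' the exact term (no ontology-graph expansion). The provenance carries the
#' anchored and total carrier counts separately, since unanchored carriers
#' are countable but not binnable.
#'
#' @param index A [genome_index()].
#' @param term A single non-empty annotation term (e.g. a GO id).
#' @return A [tagged_set()].
#' @export
query_by_annotation <- function(index, term) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  carriers <- names(index$terms)[vapply(index$terms, function(tt) term %in% tt,
                                        logical(1))]
  anchored <- index$genes$gene_id[index$genes$anchored]
  tagged_set(index$genome_id, carriers,
             provenance = list(mode = "annotation", term = term,
                               n_anchored = sum(carriers %in% anchored),
                               n_total = length(carriers)))
}

#' Tag genes by sequence homology
#'
#' Applies the e-value/identity thresholds to the hit table(s) and tags the
#' SUBJECT genes (genes of the displayed genome): external query sequences
#' are mapped onto the reference. With `bbh = TRUE` (best bidirectional
#' hit), only subjects of reciprocal best-hit pairs are tagged, which
#' requires the reverse-direction table. Subjects absent from the genome
#' are recorded as misses.
#'
#' @param index A [genome_index()].
#' @param forward [hit_table()] of external-query-vs-genome hits.
#' @param reverse Optional [hit_table()] of genome-vs-external-query hits;
#'   required when `bbh = TRUE`.
#' @param evalue_max,identity_min Thresholds passed to [filter_hits()].
#' @param bbh Require best bidirectional matches?
#' @return A [tagged_set()].
#' @export
query_by_homology <- function(index, forward, reverse = NULL,
                              evalue_max = 1e-5, identity_min = 0,
                              bbh = FALSE) {
  if (bbh && is.null(reverse))
    stop("bbh = TRUE requires a reverse hit table", call. = FALSE)
  fwd <- filter_hits(forward, evalue_max, identity_min)
  subjects <- if (bbh) {
    rev <- filter_hits(reverse, evalue_max, identity_min)
    reciprocal_best_hits(fwd, rev)$subject_id
  } else {
    unique(fwd$subject_id)
  }
  res <- .check_genome(index, unique(subjects))
  tagged_set(index$genome_id, res$hit,
             provenance = list(mode = "homology", evalue_max = evalue_max,
                               identity_min = identity_min, bbh = bbh,
                               misses = res$miss))
}

#' Intersect a tagged set with expression-based filters
#'
#' Each filter (see [filter_cv()], [filter_min_expression()],
#' [filter_deg()]) contributes an accepted-gene set; the tagged set is
#' intersected with all of them. Zero filters return the input unchanged.
#' Intersection commutes, so filter order is irrelevant.
#'
#' @param tagged A [tagged_set()].
#' @param filters List of `gene_filter` objects.
#' @return A [tagged_set()] with extended provenance.
#' @export
intersect_filters <- function(tagged, filters) {
  stopifnot(inherits(tagged, "tagged_set"))
  if (!length(filters)) return(tagged)
  ids <- tagged$gene_ids
  chain <- tagged$provenance
  for (f in filters) {
    stopifnot(inherits(f, "gene_filter"))
    ids <- intersect(ids, f$accepted)
    chain$filters <- c(chain$filters, list(f$label))
  }
  tagged_set(tagged$genome_id, ids, provenance = chain)
}

#' Write a tagged set to TSV
#'
#' Two columns: `gene_id` and a provenance hash identifying the query that
#' produced the set, so sets can be reused across CLI invocations.
#'
#' @param tagged A [tagged_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagged_tsv <- function(tagged, path) {
  hash <- provenance_hash(tagged$provenance)
  df <- data.frame(gene_id = tagged$gene_ids,
                   provenance = rep(hash, length(tagged$gene_ids)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tagged set from TSV
#' @param path Path to a file written by [write_tagged_tsv()].
#' @param genome_id Genome the set belongs to.
#' @return A [tagged_set()].
#' @export
read_tagged_tsv <- function(path, genome_id = NA_character_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  tagged_set(genome_id, df$gene_id,
             provenance = list(mode = "file",
                               hash = if (nrow(df)) df$provenance[1] else NA))
}

#' Stable hash of a provenance record
#' @param provenance Provenance list of a [tagged_set()].
#' @return MD5 hex string.
#' @export
provenance_hash <- function(provenance) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(provenance, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
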