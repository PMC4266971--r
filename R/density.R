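#' Bin index of a position
#'
#' Bins tile the chromosome as non-overlapping half-open intervals
#' `[b*width, (b+1)*width)`, so a gene at 9.5 Mb under 1 Mb binning falls
#' in bin 9 ("9-10 Mb"). Bin indices are zero-based.
#'
#' @param position Zero-based position(s), >= 0.
#' @param width Bin width (> 0) in the same unit.
#' @return Integer bin index (vectorized).
#' @export
bin_index <- function(position, width) {
  stopifnot(width > 0)
  if (any(is.na(position)) || any(position < 0))
    stop("position must be non-negative and anchored", call. = FALSE)
  as.integer(floor(position / width))
}

#' Human-readable bin labels
#'
#' Labels follow the "9-10 Mb" convention: bin b of width w spans display
#' units `b*w` to `(b+1)*w`, printed in Mb for bp genomes and cM for
#' genetic maps.
#'
#' @param bins Integer bin indices.
#' @param width Bin width in genome units.
#' @param unit `"bp"` or `"cM"`.
#' @return Character vector of labels.
#' @export
bin_label <- function(bins, width, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  scale <- if (unit == "bp") 1e6 else 1
  disp <- if (unit == "bp") "Mb" else "cM"
  lo <- bins * width / scale
  hi <- (bins + 1) * width / scale
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 10)
  paste0(fmt(lo), "-", fmt(hi), " ", disp)
}

#' Bin grid of a chromosome
#'
#' @param chrom A [chromosome_def()].
#' @param width Bin width (> 0).
#' @param unit `"bp"` or `"cM"`.
#' @return A `bin_grid`: chromosome name, width, `n_bins =
#'   ceiling(length/width)` and display labels.
#' @export
bin_grid <- function(chrom, width, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  stopifnot(inherits(chrom, "chromosome_def"), width > 0)
  n_bins <- max(1L, as.integer(ceiling(chrom$length / width)))
  structure(list(chromosome = chrom$name, width = width, unit = unit,
                 n_bins = n_bins,
                 labels = bin_label(seq_len(n_bins) - 1L, width, unit)),
            class = "bin_grid")
}

#' Build per-chromosome density tracks
#'
#' For every chromosome, counts all anchored genes and the tagged anchored
#' genes per bin and forms the relative density `tagged/all` (0 with an
#' explicit `empty` flag where a bin holds no genes, so heat maps render
#' uniformly). Unanchored genes cannot be binned and are excluded from both
#' counts; the number of tagged-but-unanchored genes is reported in
#' `attr(, "unanchored_tagged")`.
#'
#' @param index A [genome_index()].
#' @param tagged A [tagged_set()] of the same genome.
#' @return List of `density_track` objects, one per chromosome, each with
#'   fields `grid`, `all_counts`, `tagged_counts`, `relative`, `empty`.
#' @export
build_density <- function(index, tagged) {
  stopifnot(inherits(index, "genome_index"), inherits(tagged, "tagged_set"))
  if (!is.na(tagged$genome_id) && tagged$genome_id != index$genome_id)
    stop("tagged set belongs to genome '", tagged$genome_id, "', not '",
         index$genome_id, "'", call. = FALSE)
  g <- index$genes
  anch <- g[g$anchored, , drop = FALSE]
  is_tagged <- anch$gene_id %in% tagged$gene_ids
  tracks <- lapply(index$chromosomes, function(chrom) {
    grid <- bin_grid(chrom, index$bin_width, index$unit)
    on_chr <- anch$chromosome == chrom$name
    bins <- bin_index(anch$position[on_chr], index$bin_width)
    # genes exactly at chromosome length (cM rounding) fold into last bin
    bins[bins >= grid$n_bins] <- grid$n_bins - 1L
    all_counts <- tabulate(bins + 1L, nbins = grid$n_bins)
    tagged_counts <- tabulate(bins[is_tagged[on_chr]] + 1L,
                              nbins = grid$n_bins)
    empty <- all_counts == 0L
    relative <- ifelse(empty, 0, tagged_counts / pmax(all_counts, 1L))
    structure(list(grid = grid, all_counts = all_counts,
                   tagged_counts = tagged_counts, relative = relative,
                   empty = empty),
              class = "density_track")
  })
  attr(tracks, "unanchored_tagged") <-
    sum(tagged$gene_ids %in% g$gene_id[!g$anchored])
  tracks
}

#' One-sided Fisher exact test for over-representation
#'
#' For the 2x2 table
#' \preformatted{          on unit   off unit
#'   tagged       a          b
#'   untagged     c          d }
#' computes `P(X >= a)` under the hypergeometric distribution with the
#' table's fixed margins — the probability of drawing at least `a` tagged
#' genes when `a + c` genes are sampled from `a+b+c+d` of which `a + b` are
#' tagged. One-sided, over-representation only.
#'
#' @param tagged_on,tagged_off,untagged_on,untagged_off Non-negative
#'   integer cell counts, at least one positive.
#' @return The p-value in `(0, 1]`.
#' @export
fisher_one_sided <- function(tagged_on, tagged_off, untagged_on,
                             untagged_off) {
  cells <- c(tagged_on, tagged_off, untagged_on, untagged_off)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0)
    stop("all-zero contingency table", call. = FALSE)
  N <- sum(cells)
  K <- tagged_on + tagged_off      # tagged genes
  n <- tagged_on + untagged_on     # genes on the unit
  upper <- min(K, n)
  if (tagged_on > upper) stop("inconsistent table", call. = FALSE)
  # cap at 1: summing point masses can overshoot by a few ulp
  min(1, sum(stats::dhyper(tagged_on:upper, K, N - K, n)))
}

#' Chromosome(-arm) enrichment of tagged genes
#'
#' One one-sided Fisher test per unit (each chromosome, or each declared
#' arm when `unit = "arm"`), with Bonferroni adjustment over the number of
#' units actually tested. Only anchored genes enter the 2x2 tables —
#' unanchored genes have no unit. Rows are sorted by adjusted p-value,
#' ties broken by unit name.
#'
#' @param index A [genome_index()].
#' @param tagged A non-empty [tagged_set()].
#' @param unit `"chromosome"` or `"arm"`. With `"arm"`, chromosomes
#'   without a declared arm boundary contribute a single whole-chromosome
#'   unit.
#' @return An `enrichment_table` data frame with columns `unit`,
#'   `tagged_on`, `tagged_off`, `untagged_on`, `untagged_off`, `p_raw`,
#'   `p_adj`, and attribute `n_units_tested`.
#' @export
enrich <- function(index, tagged, unit = c("chromosome", "arm")) {
  unit <- match.arg(unit)
  stopifnot(inherits(index, "genome_index"), inherits(tagged, "tagged_set"))
  if (!length(tagged$gene_ids))
    stop("tagged set is empty", call. = FALSE)
  g <- index$genes[index$genes$anchored, , drop = FALSE]
  unit_of <- if (unit == "chromosome") {
    stats::setNames(g$chromosome, g$gene_id)
  } else {
    gene_arms(index)
  }
  unit_of <- unit_of[g$gene_id]
  units <- sort(unique(unname(unit_of)))
  is_tagged <- g$gene_id %in% tagged$gene_ids
  k <- length(units)
  rows <- lapply(units, function(u) {
    on <- unit_of == u
    a <- sum(is_tagged & on); b <- sum(is_tagged & !on)
    c_ <- sum(!is_tagged & on); d <- sum(!is_tagged & !on)
    p <- fisher_one_sided(a, b, c_, d)
    data.frame(unit = u, tagged_on = a, tagged_off = b, untagged_on = c_,
               untagged_off = d, p_raw = p, p_adj = min(1, p * k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_adj, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_units_tested = k,
            class = c("enrichment_table", "data.frame"))
}

#' Write density tracks to TSV
#'
#' One row per (chromosome, bin): `chromosome`, `bin_index`, `bin_label`,
#' `all_count`, `tagged_count`, `relative`, `empty_flag`.
#'
#' @param tracks List of `density_track` objects from [build_density()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(chromosome = tr$grid$chromosome,
               bin_index = seq_len(tr$grid$n_bins) - 1L,
               bin_label = tr$grid$labels,
               all_count = tr$all_counts,
               tagged_count = tr$tagged_counts,
               relative = format(tr$relative, digits = 15, trim = TRUE,
                                 scientific = FALSE),
               empty_flag = ifelse(tr$empty, "true", "false"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a density TSV back into plain data
#' @param path Path to a file written by [write_density_tsv()].
#' @return `data.frame` with the density columns, typed.
#' @export
read_density_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  df$relative <- as.numeric(df$relative)
  df$empty_flag <- df$empty_flag == "true"
  df
}

#' Write an enrichment table to TSV
#' @param table An `enrichment_table` from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  df <- as.data.frame(table)
  df$n_units_tested <- attr(table, "n_units_tested")
  df$p_raw <- format(df$p_raw, digits = 15, trim = TRUE)
  df$p_adj <- format(df$p_adj, digits = 15, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment TSV
#' @param path Path to a file written by [write_enrichment_tsv()].
#' @return `data.frame` with the enrichment columns, typed; attribute
#'   `n_units_tested` restored.
#' @export
read_enrichment_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  k <- if (nrow(df)) df$n_units_tested[1] else NA_integer_
  df$n_units_tested <- NULL
  structure(df, n_units_tested = k,
            class = c("enrichment_table", "data.frame"))
}
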