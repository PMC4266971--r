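#' Construct an expression matrix
#'
#' Genes-by-conditions matrix of non-negative expression values (the unit
#' — FPKM, TPM, counts — is the user's; no normalization is applied).
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns = conditions (colnames = condition labels).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and condition colnames",
         call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id in expression matrix", call. = FALSE)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Validate an uploaded dataset against a genome
#'
#' The offline analogue of a data-manager upload step: parses the file as
#' the declared kind, validates it, and reports unknown gene ids and
#' malformed lines. An upload whose ids have zero overlap with the genome
#' is rejected outright.
#'
#' Formats: `expression` is a TSV with header `gene_id<TAB>cond1<TAB>...`
#' and one row of non-negative reals per gene; `deg` is one gene id per
#' line (`#` comments allowed); `groups` is a two-column TSV
#' `gene_id<TAB>group`, each gene in exactly one group.
#'
#' @param path Path to the upload.
#' @param kind `"expression"`, `"deg"` or `"groups"`.
#' @param index The target [genome_index()].
#' @return List with `object` (an `expression_matrix`, `deg_list`, or
#'   `group_map`) and `report` (list with `unknown_ids`, `n_matching`).
#' @export
validate_upload <- function(path, kind = c("expression", "deg", "groups"),
                            index) {
  kind <- match.arg(kind)
  genome_ids <- index$genes$gene_id
  if (kind == "expression") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
      stop("expression upload needs a header and at least one data row",
           call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    header <- parts[[1]]
    n_cond <- length(header) - 1L
    if (n_cond < 1L)
      stop("expression upload declares no conditions", call. = FALSE)
    body <- parts[-1]
    ragged <- which(lengths(body) != n_cond + 1L)
    if (length(ragged))
      stop("ragged expression row(s) at line(s): ",
           paste(ragged + 1L, collapse = ", "), call. = FALSE)
    ids <- vapply(body, `[[`, character(1), 1L)
    vals <- t(vapply(body, function(p) {
      v <- suppressWarnings(as.numeric(p[-1]))
      v
    }, numeric(n_cond)))
    bad <- which(apply(is.na(vals), 1, any))
    if (length(bad))
      stop("non-numeric expression value(s) at line(s): ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    if (n_cond == 1L) vals <- matrix(vals, ncol = 1L)
    rownames(vals) <- ids
    colnames(vals) <- header[-1]
    object <- expression_matrix(vals)
    upload_ids <- ids
  } else if (kind == "deg") {
    lines <- trimws(readLines(path, warn = FALSE))
    ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(ids)) stop("DEG upload is empty", call. = FALSE)
    object <- structure(list(gene_ids = sort(unique(ids))),
                        class = "deg_list")
    upload_ids <- object$gene_ids
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character", quote = "",
                            col.names = c("gene_id", "group"))
    if (identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, ]
    if (!nrow(df)) stop("group upload is empty", call. = FALSE)
    conflicts <- unique(df$gene_id[duplicated(df$gene_id) &
      !duplicated(paste0(df$gene_id, "\r", df$group))])
    two_groups <- tapply(df$group, df$gene_id,
                         function(x) length(unique(x))) > 1L
    if (any(two_groups))
      stop("gene(s) assigned to more than one group: ",
           paste(names(two_groups)[two_groups], collapse = ", "),
           call. = FALSE)
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    object <- structure(list(mapping = stats::setNames(df$group, df$gene_id)),
                        class = "group_map")
    upload_ids <- df$gene_id
  }
  unknown <- setdiff(upload_ids, genome_ids)
  n_match <- length(upload_ids) - length(unknown)
  if (n_match == 0L)
    stop("no overlap with genome: none of the ", length(upload_ids),
         " uploaded ids match '", index$genome_id, "'", call. = FALSE)
  list(object = object,
       report = list(unknown_ids = unknown, n_matching = n_match))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample mean.
#' Undefined (`NA`) when the mean is zero; such genes fail every CV filter.
#'
#' @param values Numeric vector of length >= 2.
#' @return The CV, or `NA_real_` for zero-mean input.
#' @export
cv <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

.gene_filter <- function(accepted, label) {
  structure(list(accepted = sort(unique(accepted)), label = label),
            class = "gene_filter")
}

#' Expression-variation filter (CV)
#'
#' Accepts genes whose coefficient of variation across conditions is at
#' least `min_cv`. Genes absent from the matrix, and genes with undefined
#' CV (zero mean), are rejected.
#'
#' @param matrix An [expression_matrix()].
#' @param min_cv Minimum CV (>= 0).
#' @return A `gene_filter` for use with [intersect_filters()].
#' @export
filter_cv <- function(matrix, min_cv) {
  stopifnot(inherits(matrix, "expression_matrix"), min_cv >= 0)
  cvs <- apply(unclass(matrix), 1, cv)
  ok <- !is.na(cvs) & cvs >= min_cv
  .gene_filter(rownames(matrix)[ok],
               sprintf("cv>=%g", min_cv))
}

#' Minimum-expression filter
#'
#' Accepts genes whose expression surpasses (strictly exceeds) the
#' threshold in at least one condition.
#'
#' @param matrix An [expression_matrix()].
#' @param threshold Expression threshold (>= 0), in the matrix's unit.
#' @return A `gene_filter`.
#' @export
filter_min_expression <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "expression_matrix"), threshold >= 0)
  ok <- apply(unclass(matrix), 1, max) > threshold
  .gene_filter(rownames(matrix)[ok],
               sprintf("min_expr>%g", threshold))
}

#' Differential-expression membership filter
#' @param deg A validated `deg_list` (see [validate_upload()]).
#' @return A `gene_filter` accepting exactly the listed genes.
#' @export
filter_deg <- function(deg) {
  stopifnot(inherits(deg, "deg_list"))
  .gene_filter(deg$gene_ids, sprintf("deg(n=%d)", length(deg$gene_ids)))
}

#' Split a tagged set by gene groups
#'
#' Partitions the tagged genes by their group label (co-expression module,
#' cluster, ...). Genes without a group land under the reserved
#' `"ungrouped"` label. The output is a true partition of the input.
#'
#' @param tagged A [tagged_set()].
#' @param groups A validated `group_map`.
#' @return Named list of [tagged_set()] objects.
#' @export
group_partition <- function(tagged, groups) {
  stopifnot(inherits(tagged, "tagged_set"), inherits(groups, "group_map"))
  lab <- groups$mapping[tagged$gene_ids]
  lab[is.na(lab)] <- "ungrouped"
  split_ids <- split(tagged$gene_ids, lab)
  lapply(split_ids, function(ids) {
    tagged_set(tagged$genome_id, ids,
               provenance = c(tagged$provenance, list(group = TRUE)))
  })
}

#' Write an expression matrix to TSV
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
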