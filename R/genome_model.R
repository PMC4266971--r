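#' Define a chromosome
#'
#' A chromosome is described by its name, its length in the genome's
#' coordinate unit (base pairs for physical maps, centiMorgan for genetic
#' maps) and an optional centromere/arm boundary. Positions strictly below
#' the boundary belong to the short arm ("S"); positions at or above it
#' belong to the long arm ("L") — the boundary itself is assigned to the
#' long arm because genome releases never state the cut convention.
#'
#' @param name Chromosome name, e.g. `"3B"` or `"chr1"`.
#' @param length Chromosome length (> 0) in the genome unit.
#' @param arm_boundary Optional arm boundary, strictly inside `(0, length)`.
#'   `NA` (default) declares a chromosome without arm-sorted data; such a
#'   chromosome is a single enrichment unit.
#' @return An object of class `chromosome_def`.
#' @export
chromosome_def <- function(name, length, arm_boundary = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0)
    stop("chromosome '", name, "': length must be > 0", call. = FALSE)
  arm_boundary <- as.numeric(arm_boundary)
  if (!is.na(arm_boundary) && (arm_boundary <= 0 || arm_boundary >= length))
    stop("chromosome '", name, "': arm_boundary must lie strictly inside (0, length)",
         call. = FALSE)
  structure(list(name = name, length = length, arm_boundary = arm_boundary),
            class = "chromosome_def")
}

#' Construct a validated genome index
#'
#' The central container of the package: chromosome definitions, the gene
#' table (anchored and unanchored genes), per-gene annotation terms,
#' optional gene sequences, and the binning policy (coordinate unit and bin
#' width). Positions are stored zero-based internally; file readers perform
#' the 1-based-to-0-based shift for bp genomes.
#'
#' @param genome_id Identifier for the genome.
#' @param unit Coordinate unit, `"bp"` or `"cM"`; shared by all chromosomes.
#' @param bin_width Bin width in `unit` (> 0). Conventional choices are
#'   1 Mb or 10 Mb for physical maps and 5 cM for genetic maps.
#' @param chromosomes List of [chromosome_def()] objects.
#' @param genes `data.frame` with columns `gene_id`, `chromosome`,
#'   `position` (zero-based, in `unit`), `anchored`.
#' @param terms Named list mapping `gene_id` to a character vector of
#'   annotation terms (GO/PFAM-style).
#' @param sequences Named character vector of gene sequences.
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome_id, unit = c("bp", "cM"), bin_width,
                         chromosomes, genes, terms = list(),
                         sequences = character()) {
  unit <- match.arg(unit)
  bin_width <- as.numeric(bin_width)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  if (inherits(chromosomes, "chromosome_def")) chromosomes <- list(chromosomes)
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1L)
  names(chromosomes) <- vapply(chromosomes, `[[`, character(1), "name")
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome names", call. = FALSE)

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chromosome", "position", "anchored")
  if (!all(needed %in% names(genes)))
    stop("gene table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  # anchored <=> chromosome and position both present
  has_loc <- !is.na(genes$chromosome) & !is.na(genes$position)
  if (any(genes$anchored != has_loc))
    stop("anchored flag inconsistent with chromosome/position for gene(s): ",
         paste(genes$gene_id[genes$anchored != has_loc], collapse = ", "),
         call. = FALSE)
  bad_chr <- setdiff(unique(genes$chromosome[has_loc]), names(chromosomes))
  if (length(bad_chr))
    stop("unknown chromosome name(s): ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  chr_len <- vapply(chromosomes, `[[`, numeric(1), "length")
  anch <- which(has_loc)
  too_far <- anch[genes$position[anch] < 0 |
                  genes$position[anch] >= chr_len[genes$chromosome[anch]]]
  if (length(too_far))
    stop("position beyond chromosome length for gene(s): ",
         paste(genes$gene_id[too_far], collapse = ", "), call. = FALSE)
  rownames(genes) <- NULL

  if (length(terms)) {
    unknown <- setdiff(names(terms), genes$gene_id)
    if (length(unknown))
      stop("terms refer to unknown gene(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  structure(list(genome_id = genome_id, unit = unit, bin_width = bin_width,
                 chromosomes = chromosomes, genes = genes, terms = terms,
                 sequences = sequences),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index '", x$genome_id, "' (", x$unit, ", bin width ",
      format(x$bin_width, scientific = FALSE), " ", x$unit, ")\n", sep = "")
  cat("  chromosomes:", length(x$chromosomes), "| genes:", nrow(x$genes),
      "(", sum(x$genes$anchored), "anchored )\n")
  cat("  annotated genes:", length(x$terms),
      "| sequences:", length(x$sequences), "\n")
  invisible(x)
}

#' Read a genome configuration file
#'
#' JSON with fields `genome_id`, `unit` ("bp" or "cM"), `bin_width` and
#' `chromosomes`, a list of objects with `name`, `length` and optional
#' `arm_boundary`.
#'
#' @param path Path to the JSON configuration.
#' @return A list with `genome_id`, `unit`, `bin_width`, `chromosomes`
#'   (list of [chromosome_def()]).
#' @export
read_genome_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("genome_id", "unit", "bin_width", "chromosomes"))
    if (is.null(cfg[[f]]))
      stop("genome config missing field '", f, "'", call. = FALSE)
  chroms <- lapply(cfg$chromosomes, function(ch) {
    chromosome_def(ch$name, ch$length,
                   if (is.null(ch$arm_boundary)) NA_real_ else ch$arm_boundary)
  })
  list(genome_id = cfg$genome_id, unit = cfg$unit,
       bin_width = as.numeric(cfg$bin_width), chromosomes = chroms,
       files = cfg$files)
}

#' Load a genome from its configuration file
#'
#' Convenience loader for the CLI: reads the config, then the anchor table
#' and any `fasta`/`annotations` files declared in the config's `files`
#' field (paths resolved relative to the config file).
#'
#' @param config_path Path to a genome config JSON declaring at least
#'   `files$anchors`.
#' @return A [genome_index()].
#' @export
load_genome <- function(config_path) {
  cfg <- read_genome_config(config_path)
  if (is.null(cfg$files) || is.null(cfg$files$anchors))
    stop("genome config '", config_path,
         "' declares no anchor table (files.anchors)", call. = FALSE)
  rel <- function(p) if (file.exists(p)) p
         else file.path(dirname(config_path), p)
  anchors <- rel(cfg$files$anchors)
  index <- if (grepl("\\.gff3?$", anchors, ignore.case = TRUE)) {
    load_anchor_gff3(anchors, cfg)
  } else {
    load_anchor_table(anchors, cfg)
  }
  if (!is.null(cfg$files$fasta))
    index <- load_fasta(rel(cfg$files$fasta), index)
  if (!is.null(cfg$files$annotations))
    index <- suppressWarnings(load_annotations(rel(cfg$files$annotations),
                                               index))
  index
}

#' Write a genome configuration file
#' @param config List as returned by [read_genome_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_config <- function(config, path) {
  chroms <- lapply(config$chromosomes, function(ch) {
    out <- list(name = ch$name, length = ch$length)
    if (!is.na(ch$arm_boundary)) out$arm_boundary <- ch$arm_boundary
    out
  })
  out <- list(genome_id = config$genome_id, unit = config$unit,
              bin_width = config$bin_width, chromosomes = chroms)
  if (!is.null(config$files)) out$files <- config$files
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a gene anchor table
#'
#' Reads the tab-separated anchor format: header
#' `gene_id  chromosome  arm  position  anchored`, one row per gene.
#' Unanchored genes leave `chromosome` and `position` empty and carry
#' `anchored = false`; they are retained (they are countable but not
#' binnable). Positions in bp files are 1-based and shifted to the
#' package's internal 0-based convention; cM positions are taken as given.
#'
#' @param path Path to the anchor TSV.
#' @param genome_config Genome header as from [read_genome_config()]:
#'   `genome_id`, `unit`, `bin_width`, `chromosomes`.
#' @return A validated [genome_index()].
#' @export
load_anchor_table <- function(path, genome_config) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("", "NA"), quote = "")
  needed <- c("gene_id", "chromosome", "arm", "position", "anchored")
  if (!all(needed %in% names(tab)))
    stop("anchor table must have header columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stop("duplicate gene_id in anchor table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  position <- suppressWarnings(as.numeric(tab$position))
  bad_num <- which(!is.na(tab$position) & is.na(position))
  if (length(bad_num))
    stop("non-numeric position at row(s): ", paste(bad_num, collapse = ", "),
         call. = FALSE)
  anchored <- tolower(tab$anchored) %in% c("true", "t", "1", "yes")

  chroms <- genome_config$chromosomes
  names(chroms) <- vapply(chroms, `[[`, character(1), "name")
  chr_len <- vapply(chroms, `[[`, numeric(1), "length")
  unknown <- setdiff(unique(tab$chromosome[!is.na(tab$chromosome)]),
                     names(chroms))
  if (length(unknown))
    stop("unknown chromosome name(s) in anchor table: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  pos0 <- position
  if (genome_config$unit == "bp") {
    ok <- is.na(position) | (position >= 1 &
                             position <= chr_len[tab$chromosome])
    pos0 <- position - 1
  } else {
    ok <- is.na(position) | (position >= 0 &
                             position <= chr_len[tab$chromosome])
    # a cM position exactly at chromosome length (rounding) -> last bin;
    # nudge onto the half-open domain
    at_end <- which(!is.na(position) & position == chr_len[tab$chromosome])
    pos0[at_end] <- position[at_end] - 1e-9
  }
  if (any(!ok, na.rm = TRUE))
    stop("position beyond chromosome length at row(s): ",
         paste(which(!ok), collapse = ", "), call. = FALSE)

  genes <- data.frame(gene_id = tab$gene_id, chromosome = tab$chromosome,
                      position = pos0, anchored = anchored,
                      stringsAsFactors = FALSE)
  genome_index(genome_config$genome_id, genome_config$unit,
               genome_config$bin_width, chroms, genes)
}

#' Write a gene anchor table
#'
#' Inverse of [load_anchor_table()]: positions are emitted 1-based for bp
#' genomes so that load/write round-trips reproduce the file's semantic
#' content (row order excepted).
#'
#' @param index A [genome_index()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(index, path) {
  g <- index$genes
  pos_out <- g$position
  if (index$unit == "bp") pos_out <- pos_out + 1
  arms <- rep(NA_character_, nrow(g))
  if (nrow(g)) {
    idx <- which(g$anchored)
    arms[idx] <- vapply(idx, function(i) {
      ch <- index$chromosomes[[g$chromosome[i]]]
      if (is.na(ch$arm_boundary)) NA_character_
      else if (g$position[i] < ch$arm_boundary) "S" else "L"
    }, character(1))
  }
  out <- data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                    arm = arms,
                    position = ifelse(is.na(pos_out), NA,
                                      format(pos_out, scientific = FALSE,
                                             trim = TRUE, digits = 15)),
                    anchored = ifelse(g$anchored, "true", "false"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Load gene anchors from a GFF3 file
#'
#' Alternative reader: features of type `gene` are taken, the gene id comes
#' from the `ID` attribute, and the anchoring position is the feature
#' midpoint (rounded down). All GFF3 genes are anchored by construction.
#'
#' @inheritParams load_anchor_table
#' @return A validated [genome_index()].
#' @export
load_anchor_gff3 <- function(path, genome_config) {
  if (genome_config$unit != "bp")
    stop("GFF3 anchors require a bp genome", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 gene feature without ID attribute", call. = FALSE)
  mid <- floor((BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2)
  chroms <- genome_config$chromosomes
  names(chroms) <- vapply(chroms, `[[`, character(1), "name")
  genes <- data.frame(gene_id = ids,
                      chromosome = as.character(GenomeInfoDb::seqnames(gr)),
                      position = mid - 1,  # 1-based midpoint -> 0-based
                      anchored = TRUE, stringsAsFactors = FALSE)
  genome_index(genome_config$genome_id, genome_config$unit,
               genome_config$bin_width, chroms, genes)
}

#' Attach annotation terms to a genome index
#'
#' Reads a two-column TSV `gene_id<TAB>term` (GO/PFAM-style, no header
#' required; a `gene_id`/`term` header row is tolerated). Terms accumulate
#' per gene. Rows naming genes absent from the index are collected into a
#' warning report rather than dropped silently; rows with an empty term are
#' rejected with a warning.
#'
#' @param path Path to the annotation TSV.
#' @param index A [genome_index()].
#' @return The updated index. The attached report is available as
#'   `attr(, "annotation_report")`: a list with `unknown_ids` and
#'   `rejected_rows`.
#' @export
load_annotations <- function(path, index) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  report <- list(unknown_ids = character(), rejected_rows = integer())
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (identical(tolower(parts[[1]][1]), "gene_id")) {
      parts <- parts[-1]
    }
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) < 2L || !nzchar(p[2])) {
        report$rejected_rows <- c(report$rejected_rows, i)
        next
      }
      gid <- p[1]; term <- p[2]
      if (!gid %in% index$genes$gene_id) {
        report$unknown_ids <- c(report$unknown_ids, gid)
        next
      }
      index$terms[[gid]] <- union(index$terms[[gid]], term)
    }
  }
  report$unknown_ids <- unique(report$unknown_ids)
  if (length(report$unknown_ids))
    warning("annotation rows for unknown gene(s): ",
            paste(report$unknown_ids, collapse = ", "), call. = FALSE)
  if (length(report$rejected_rows))
    warning("rejected annotation row(s) with empty term: ",
            paste(report$rejected_rows, collapse = ", "), call. = FALSE)
  attr(index, "annotation_report") <- report
  index
}

#' Attach gene sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Records whose id matches no gene in the index are kept in an "orphan
#' sequences" report (partial sequence sets are legitimate: exports may
#' cover only tagged genes). Duplicate FASTA ids are a hard error.
#'
#' @param path Path to a FASTA file.
#' @param index A [genome_index()].
#' @return The updated index; orphans under `attr(, "orphan_sequences")`
#'   (named character vector).
#' @export
load_fasta <- function(path, index) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id: ", paste(dup, collapse = ", "), call. = FALSE)
  vals <- as.character(seqs)
  names(vals) <- ids
  known <- ids %in% index$genes$gene_id
  index$sequences[ids[known]] <- vals[known]
  attr(index, "orphan_sequences") <- vals[!known]
  index
}

#' Write gene sequences to FASTA
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Arm unit of a position on a chromosome
#'
#' Returns `"<chrom>S"` for positions strictly below the arm boundary,
#' `"<chrom>L"` at or above it, and the bare chromosome name when no
#' boundary is declared.
#'
#' @param chrom A [chromosome_def()].
#' @param position Zero-based position(s) on the chromosome.
#' @return Character vector of arm unit labels.
#' @export
arm_of <- function(chrom, position) {
  stopifnot(inherits(chrom, "chromosome_def"))
  if (any(is.na(position)))
    stop("arm_of requires an anchored position", call. = FALSE)
  if (is.na(chrom$arm_boundary)) return(rep(chrom$name, length(position)))
  ifelse(position < chrom$arm_boundary,
         paste0(chrom$name, "S"), paste0(chrom$name, "L"))
}

#' Arm unit for every anchored gene of a genome
#'
#' @param index A [genome_index()].
#' @return Named character vector (gene_id -> arm unit) over anchored genes.
#' @export
gene_arms <- function(index) {
  g <- index$genes[index$genes$anchored, , drop = FALSE]
  if (!nrow(g)) return(stats::setNames(character(), character()))
  out <- vapply(seq_len(nrow(g)), function(i) {
    arm_of(index$chromosomes[[g$chromosome[i]]], g$position[i])
  }, character(1))
  stats::setNames(out, g$gene_id)
}
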