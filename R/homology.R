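#' Construct a hit table
#'
#' A hit table is a data frame of pairwise alignment hits in the 12-column
#' tabular layout (query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score), optionally labelled with a search direction.
#'
#' @param hits `data.frame` with the 12 standard columns.
#' @param direction `"forward"` or `"reverse"` label (bookkeeping only).
#' @return An object of class `hit_table` (a data frame).
#' @export
hit_table <- function(hits = NULL, direction = "forward") {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  if (is.null(hits) || !nrow(as.data.frame(hits))) {
    hits <- as.data.frame(stats::setNames(
      list(character(), character(), numeric(), integer(), integer(),
           integer(), integer(), integer(), integer(), integer(),
           numeric(), numeric()), cols))
  }
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (!all(cols %in% names(hits)))
    stop("hit table needs columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  hits <- hits[, cols]
  if (nrow(hits)) {
    if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
      stop("pct_identity must lie in [0, 100]", call. = FALSE)
    if (any(hits$evalue < 0))
      stop("evalue must be >= 0", call. = FALSE)
    if (any(hits$aln_length <= 0))
      stop("aln_length must be positive", call. = FALSE)
  }
  rownames(hits) <- NULL
  structure(hits, direction = direction,
            class = c("hit_table", "data.frame"))
}

#' Parse a tabular alignment hit file
#'
#' Reads whitespace- or tab-separated 12-column rows (BLAST "outfmt 6"
#' dialect). Lines starting with `#` are comments. Rows with fewer than 12
#' columns or with non-numeric numeric fields are rejected, and the
#' offending line numbers are reported in a warning and in
#' `attr(, "rejected_lines")`.
#'
#' @param path Path to the hit file.
#' @param direction Direction label for the resulting table.
#' @return A [hit_table()].
#' @export
parse_tabular_hits <- function(path, direction = "forward") {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  rejected <- integer()
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12L) { rejected <- c(rejected, lineno[i]); next }
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(num)) { rejected <- c(rejected, lineno[i]); next }
    rows[[i]] <- data.frame(
      query_id = p[1], subject_id = p[2], pct_identity = num[1],
      aln_length = as.integer(num[2]), mismatches = as.integer(num[3]),
      gap_opens = as.integer(num[4]), q_start = as.integer(num[5]),
      q_end = as.integer(num[6]), s_start = as.integer(num[7]),
      s_end = as.integer(num[8]), evalue = num[9], bitscore = num[10],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (length(rejected))
    warning("rejected malformed hit row(s) at line(s): ",
            paste(rejected, collapse = ", "), call. = FALSE)
  out <- hit_table(tab, direction = direction)
  attr(out, "rejected_lines") <- rejected
  out
}

#' Write a hit table in the 12-column tabular dialect
#' @param table A [hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(table, path) {
  df <- as.data.frame(table)
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  df$pct_identity <- formatC(df$pct_identity, format = "f", digits = 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter hits by e-value and identity thresholds
#'
#' Keeps hits with `evalue <= evalue_max` and `pct_identity >=
#' identity_min`. Both bounds are inclusive ("at least 70%" identity keeps
#' a 70.0% hit). Row order is preserved; the operation is idempotent.
#'
#' @param table A [hit_table()].
#' @param evalue_max Maximum e-value (> 0).
#' @param identity_min Minimum percent identity in `[0, 100]`.
#' @return The filtered [hit_table()].
#' @export
filter_hits <- function(table, evalue_max, identity_min) {
  stopifnot(inherits(table, "hit_table"), evalue_max > 0,
            identity_min >= 0, identity_min <= 100)
  keep <- table$evalue <= evalue_max & table$pct_identity >= identity_min
  hit_table(as.data.frame(table)[keep, , drop = FALSE],
            direction = attr(table, "direction"))
}

#' Best hit per query
#'
#' For each query, the hit with maximal bit score. Ties are broken
#' deterministically: lower e-value, then higher identity, then
#' lexicographically smallest subject id.
#'
#' @param table A [hit_table()].
#' @return A [hit_table()] with one row per query id.
#' @export
best_hit_per_query <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  df <- as.data.frame(table)
  if (!nrow(df)) return(table)
  ord <- order(df$query_id, -df$bitscore, df$evalue, -df$pct_identity,
               df$subject_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$query_id), , drop = FALSE]
  hit_table(df, direction = attr(table, "direction"))
}

#' Reciprocal best hits (best bidirectional hits)
#'
#' The classic ortholog heuristic: a pair `(a, b)` is kept iff `b` is the
#' best hit of `a` in the forward table and `a` is the best hit of `b` in
#' the reverse table. The result is a one-to-one partial matching.
#'
#' @param forward [hit_table()] of A-vs-B hits.
#' @param reverse [hit_table()] of B-vs-A hits.
#' @return `data.frame` with columns `query_id`, `subject_id`.
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  bf <- best_hit_per_query(forward)
  br <- best_hit_per_query(reverse)
  rev_map <- stats::setNames(br$subject_id, br$query_id)
  keep <- !is.na(rev_map[bf$subject_id]) &
    rev_map[bf$subject_id] == bf$query_id
  out <- data.frame(query_id = bf$query_id[keep],
                    subject_id = bf$subject_id[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- built-in nucleotide search -------------------------------------------

.nuc_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encode_nuc <- function(seq, label) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- .nuc_codes[chars]
  if (anyNA(codes))
    stop("non-IUPAC residue in sequence '", label, "': ",
         paste(unique(chars[is.na(codes)]), collapse = ", "), call. = FALSE)
  unname(codes)
}

.revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

# ungapped seed-and-extend between two encoded sequences; returns the best
# local hit (score, matches, extents) over the supplied seed positions
.extend_best <- function(qv, sv, seeds_q, seeds_s, k) {
  best <- NULL
  diag <- seeds_s - seeds_q
  first <- !duplicated(diag)
  for (idx in which(first)) {
    qp <- seeds_q[idx]; sp <- seeds_s[idx]
    # right extension
    score <- 0; m <- 0; best_r <- 0; mr <- 0; lr <- 0
    i <- qp + k; j <- sp + k
    nq <- length(qv); ns <- length(sv)
    while (i <= nq && j <= ns) {
      hit <- qv[i] == sv[j] && qv[i] != 5L
      score <- score + if (hit) 1 else -2
      m <- m + hit
      if (score > best_r) { best_r <- score; mr <- m; lr <- i - (qp + k) + 1 }
      if (score < best_r - 20) break  # X-drop
      i <- i + 1; j <- j + 1
    }
    # left extension
    score <- 0; m <- 0; best_l <- 0; ml <- 0; ll <- 0
    i <- qp - 1; j <- sp - 1
    while (i >= 1 && j >= 1) {
      hit <- qv[i] == sv[j] && qv[i] != 5L
      score <- score + if (hit) 1 else -2
      m <- m + hit
      if (score > best_l) { best_l <- score; ml <- m; ll <- qp - i }
      if (score < best_l - 20) break
      i <- i - 1; j <- j - 1
    }
    tot <- k + best_r + best_l
    if (is.null(best) || tot > best$score) {
      best <- list(score = tot, matches = k + mr + ml,
                   q_start = qp - ll, q_end = qp + k - 1 + lr,
                   s_start = sp - ll, s_end = sp + k - 1 + lr)
    }
  }
  best
}

.kmer_keys <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(toupper(seq), 1:(n - k + 1), k:n)
}

#' Built-in lightweight nucleotide search
#'
#' A self-contained stand-in for an external nucleotide aligner so the test
#' suite needs no external binary: exact k-mer seeding on both strands
#' followed by ungapped extension under a +1/-2 match/mismatch score. One
#' best local hit is reported per (query, subject) pair. The bit score is
#' the raw ungapped score and the e-value is the crude surrogate
#' `m * n * 2^(-score)` (m = query length, n = total subject length); these
#' are NOT comparable to BLAST statistics and exist only so thresholding
#' and best-hit logic can be exercised end to end. Imported tabular hit
#' files are the production path for real analyses.
#'
#' Minus-strand hits are reported with `s_start > s_end`, following the
#' tabular-format convention.
#'
#' @param queries Named character vector of nucleotide sequences (A/C/G/T/N).
#' @param subjects Named character vector of nucleotide sequences.
#' @param k Seed length (>= 8).
#' @param min_identity Hits below this percent identity are dropped.
#' @param direction Direction label for the resulting table.
#' @return A [hit_table()].
#' @export
naive_search <- function(queries, subjects, k = 11L, min_identity = 0,
                         direction = "forward") {
  stopifnot(k >= 8, length(subjects) >= 1L, length(queries) >= 1L)
  if (is.null(names(queries)) || is.null(names(subjects)))
    stop("queries and subjects must be named", call. = FALSE)
  sv <- lapply(seq_along(subjects),
               function(i) .encode_nuc(subjects[[i]], names(subjects)[i]))
  # seed index over subjects: kmer -> encoded (subject_idx, position)
  keys <- character(); enc <- numeric()
  for (i in seq_along(subjects)) {
    kk <- .kmer_keys(subjects[[i]], k)
    ok <- !grepl("N", kk, fixed = TRUE)
    keys <- c(keys, kk[ok])
    enc <- c(enc, i * 1e7 + which(ok))
  }
  index <- if (length(keys)) list2env(split(enc, keys)) else new.env()
  n_total <- sum(nchar(subjects))

  out <- list()
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") queries[[qi]] else .revcomp(queries[[qi]])
      qv <- .encode_nuc(qseq, qname)
      kk <- .kmer_keys(qseq, k)
      seeds_by_subj <- list()
      for (qp in seq_along(kk)) {
        hit <- get0(kk[qp], envir = index, inherits = FALSE)
        if (is.null(hit)) next
        for (e in hit) {
          si <- e %/% 1e7; sp <- e %% 1e7
          key <- as.character(si)
          seeds_by_subj[[key]] <- rbind(seeds_by_subj[[key]], c(qp, sp))
        }
      }
      for (key in names(seeds_by_subj)) {
        si <- as.integer(key)
        seeds <- seeds_by_subj[[key]]
        best <- .extend_best(qv, sv[[si]], seeds[, 1], seeds[, 2], k)
        if (is.null(best)) next
        alen <- best$q_end - best$q_start + 1
        ident <- best$matches / alen * 100
        if (ident < min_identity) next
        qlen <- nchar(queries[[qi]])
        # coordinates back to the original (plus-strand) query frame
        if (strand == "+") {
          q1 <- best$q_start; q2 <- best$q_end
          s1 <- best$s_start; s2 <- best$s_end
        } else {
          q1 <- qlen - best$q_end + 1; q2 <- qlen - best$q_start + 1
          s1 <- best$s_end; s2 <- best$s_start  # s_start > s_end on minus
        }
        cand <- data.frame(
          query_id = qname, subject_id = names(subjects)[si],
          pct_identity = round(ident, 2), aln_length = alen,
          mismatches = alen - best$matches, gap_opens = 0L,
          q_start = q1, q_end = q2, s_start = s1, s_end = s2,
          evalue = qlen * n_total * 2^(-best$score),
          bitscore = best$score, stringsAsFactors = FALSE)
        pair <- paste0(qname, "\r", names(subjects)[si])
        if (is.null(out[[pair]]) || cand$bitscore > out[[pair]]$bitscore)
          out[[pair]] <- cand
      }
    }
  }
  tab <- if (length(out)) do.call(rbind, unname(out)) else NULL
  res <- hit_table(tab, direction = direction)
  if (nrow(res)) {
    df <- as.data.frame(res)
    df <- df[order(df$query_id, -df$bitscore, df$subject_id), , drop = FALSE]
    res <- hit_table(df, direction = direction)
  }
  res
}
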