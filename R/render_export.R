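#' Heat map rendering specification
#'
#' Controls geometry and panel mode of the chromosome heat map. The color
#' ramp runs linearly from white (0) to a single saturated hue at the
#' global maximum of the plotted value across all tracks of the figure;
#' empty bins are drawn in a reserved neutral grey.
#'
#' @param value Which per-bin value to plot: `"relative"` (tagged/all),
#'   `"all"` (gene counts) or `"tagged"` (tagged counts).
#' @param px_per_bin Rectangle width in pixels.
#' @param track_height Rectangle height in pixels.
#' @param high Hex color of the ramp's saturated end.
#' @param empty_color Hex color for bins with no genes.
#' @return An object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(value = c("relative", "all", "tagged"),
                         px_per_bin = 14, track_height = 22,
                         high = "#b30000", empty_color = "#dddddd") {
  value <- match.arg(value)
  structure(list(value = value, px_per_bin = px_per_bin,
                 track_height = track_height, high = high,
                 empty_color = empty_color),
            class = "heatmap_spec")
}

.ramp_color <- function(v, vmax, high) {
  if (vmax <= 0) vmax <- 1
  f <- grDevices::colorRamp(c("#ffffff", high))
  rgb <- f(pmin(1, pmax(0, v / vmax)))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

.track_value <- function(tr, value) {
  switch(value, relative = tr$relative, all = tr$all_counts,
         tagged = tr$tagged_counts)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render chromosome heat maps to SVG
#'
#' One row per chromosome, one rectangle per bin, colored by the plotted
#' value on a monotone white-to-hue ramp scaled to the global maximum over
#' all panels (the scaling choice is recorded in the legend). Each bin
#' rectangle carries a `<title>` element reporting the bin label and the
#' absolute and relative tagged counts — the static counterpart of an
#' interactive tooltip. Passing a named list of track lists stacks one
#' panel per name (per-group mode) sharing the coordinate axis.
#'
#' @param tracks List of `density_track` objects from [build_density()],
#'   or a named list of such lists for per-group panels.
#' @param spec A [heatmap_spec()].
#' @param out Output SVG path.
#' @return `out`, invisibly.
#' @export
render_heatmap <- function(tracks, spec = heatmap_spec(), out) {
  stopifnot(inherits(spec, "heatmap_spec"))
  panels <- if (length(tracks) && inherits(tracks[[1]], "density_track")) {
    list(tracks = tracks)
  } else tracks
  if (!length(panels) || !length(panels[[1]]))
    stop("render_heatmap needs at least one track", call. = FALSE)
  all_tracks <- unlist(panels, recursive = FALSE)
  vmax <- max(vapply(all_tracks,
                     function(tr) max(.track_value(tr, spec$value), 0),
                     numeric(1)))

  label_w <- 90; pad <- 12; legend_h <- 54
  row_h <- spec$track_height + 6
  max_bins <- max(vapply(all_tracks, function(tr) tr$grid$n_bins, integer(1)))
  width <- label_w + max_bins * spec$px_per_bin + 2 * pad
  n_rows <- sum(lengths(panels))
  height <- pad + length(panels) * 20 + n_rows * row_h + legend_h + pad

  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
    width, round(height)))
  y <- pad
  for (pi in seq_along(panels)) {
    pname <- names(panels)[pi]
    if (!is.null(pname) && nzchar(pname)) {
      svg <- c(svg, sprintf(
        '<text x="%d" y="%d" font-size="13" font-family="sans-serif" font-weight="bold">%s</text>',
        pad, y + 13, .xml_escape(pname)))
    }
    y <- y + 20
    for (tr in panels[[pi]]) {
      vals <- .track_value(tr, spec$value)
      cols <- .ramp_color(vals, vmax, spec$high)
      cols[tr$empty] <- spec$empty_color
      svg <- c(svg, sprintf(
        '<text x="%d" y="%.1f" font-size="12" font-family="sans-serif">%s</text>',
        pad, y + spec$track_height / 2 + 4,
        .xml_escape(tr$grid$chromosome)))
      for (b in seq_len(tr$grid$n_bins)) {
        tip <- sprintf("%s %s: tagged %d/%d (%.4g)", tr$grid$chromosome,
                       tr$grid$labels[b], tr$tagged_counts[b],
                       tr$all_counts[b], tr$relative[b])
        svg <- c(svg, sprintf(
          '<rect class="bin" x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" stroke="#999" stroke-width="0.5"><title>%s</title></rect>',
          label_w + (b - 1) * spec$px_per_bin, y, spec$px_per_bin,
          spec$track_height, cols[b], .xml_escape(tip)))
      }
      y <- y + row_h
    }
  }
  # legend: discrete ramp swatches + scale annotation
  y <- y + 10
  n_sw <- 10
  for (i in seq_len(n_sw)) {
    svg <- c(svg, sprintf(
      '<rect class="legend" x="%.1f" y="%.1f" width="16" height="12" fill="%s" stroke="#999" stroke-width="0.5"/>',
      pad + (i - 1) * 16, y,
      .ramp_color((i - 1) / (n_sw - 1) * vmax, vmax, spec$high)))
  }
  svg <- c(svg, sprintf(
    '<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif">0</text>',
    pad, y + 24))
  svg <- c(svg, sprintf(
    '<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif">%s (%s; global max over all panels)</text>',
    pad + n_sw * 16 + 6, y + 10, format(vmax, digits = 4), spec$value))
  svg <- c(svg, "</svg>")
  ok <- tryCatch({ writeLines(svg, out); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SVG to '", out, "'", call. = FALSE)
  invisible(out)
}

#' Export the sequences of a bin's tagged genes as FASTA
#'
#' Writes the tagged genes whose position falls into the given bin of the
#' given chromosome, ordered by position then id, with gene ids as FASTA
#' headers. Tagged genes in the bin lacking a loaded sequence are a hard
#' error. An empty bin yields an empty file and a warning.
#'
#' @param index A [genome_index()] with sequences loaded.
#' @param tagged A [tagged_set()].
#' @param chromosome Chromosome name.
#' @param bin Zero-based bin index.
#' @param out Output FASTA path.
#' @return `out`, invisibly; gene ids exported as `attr(, "gene_ids")`.
#' @export
export_bin_fasta <- function(index, tagged, chromosome, bin, out) {
  stopifnot(inherits(index, "genome_index"), inherits(tagged, "tagged_set"))
  if (!chromosome %in% names(index$chromosomes))
    stop("unknown chromosome '", chromosome, "'", call. = FALSE)
  grid <- bin_grid(index$chromosomes[[chromosome]], index$bin_width,
                   index$unit)
  if (bin < 0 || bin >= grid$n_bins)
    stop("bin ", bin, " out of range for chromosome '", chromosome,
         "' (0-", grid$n_bins - 1L, ")", call. = FALSE)
  g <- index$genes
  sel <- g$anchored & g$chromosome == chromosome &
    g$gene_id %in% tagged$gene_ids
  sel[sel] <- bin_index(g$position[sel], index$bin_width) == bin
  hits <- g[sel, , drop = FALSE]
  hits <- hits[order(hits$position, hits$gene_id), , drop = FALSE]
  if (!nrow(hits)) {
    warning("no tagged genes in bin ", bin, " of chromosome '",
            chromosome, "'", call. = FALSE)
    file.create(out)
    return(invisible(structure(out, gene_ids = character())))
  }
  missing <- setdiff(hits$gene_id, names(index$sequences))
  if (length(missing))
    stop("no sequence loaded for tagged gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  write_fasta(index$sequences[hits$gene_id], out)
  invisible(structure(out, gene_ids = hits$gene_id))
}

#' Write the standard report files of a run
#'
#' Writes `density.tsv`, `enrichment.tsv` and `tagged.tsv` in the dialects
#' understood by [read_density_tsv()], [read_enrichment_tsv()] and
#' [read_tagged_tsv()], so every report round-trips.
#'
#' @param tracks List of `density_track` objects.
#' @param enrichment An `enrichment_table`.
#' @param tagged A [tagged_set()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_reports <- function(tracks, enrichment, tagged, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(density = file.path(out_dir, "density.tsv"),
             enrichment = file.path(out_dir, "enrichment.tsv"),
             tagged = file.path(out_dir, "tagged.tsv"))
  write_density_tsv(tracks, paths[["density"]])
  write_enrichment_tsv(enrichment, paths[["enrichment"]])
  write_tagged_tsv(tagged, paths[["tagged"]])
  invisible(paths)
}
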