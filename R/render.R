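# Headless figure generation for the four display types: scatter, split
# scatter, violin, heatmap. Every renderer writes the figure (SVG via
# cairo, or PNG, chosen by file extension) plus a JSON render report
# sidecar (<out>.report.json). The report — point counts, legend entries,
# axis ranges, tile values — is the testable surface; pixels never are.

open_device <- function(out, width, height) {
  if (grepl("\\.svg$", out)) {
    grDevices::svg(out, width = width / 96, height = height / 96)
  } else if (grepl("\\.png$", out)) {
    grDevices::png(out, width = width, height = height, type = "cairo")
  } else {
    sb_stop("unsupported figure format for '%s' (use .svg or .png)", out)
  }
}

write_report <- function(report, out) {
  write_json_file(report, paste0(out, ".report.json"))
  report
}

# resolve a color source against a bundle: metadata field or gene
resolve_colors <- function(bundle, color_by, palette = NULL) {
  field <- bundle$cells$fields[[color_by]]
  if (!is.null(field)) {
    if (field$kind == "categorical") {
      lev <- names(field$value_dict)
      cols <- field$color_map
      if (!is.null(palette)) cols <- assign_colors(field, palette)$color_map
      legend <- data.frame(label = lev, color = unname(cols[lev]),
                           count = unname(as.integer(field$counts[lev])),
                           stringsAsFactors = FALSE)
      return(list(kind = "field", name = color_by,
                  point_colors = unname(cols[lev][field$values + 1L]),
                  legend = legend))
    }
    if (field$kind == "numeric") {
      v <- field$values
      v[is.na(v)] <- 0
      d <- discretize_expression(v, n_bins = bundle$manifest$bins)
      leg <- assign_colors(d$legend, palette %||% bundle$manifest$palettes$expression)
      legend <- data.frame(label = legend_bin_labels(leg),
                           color = leg$bin_colors,
                           count = leg$bin_counts, stringsAsFactors = FALSE)
      return(list(kind = "field", name = color_by,
                  point_colors = leg$bin_colors[d$bin + 1L], legend = legend))
    }
    sb_stop("cannot color by uniqueId field '%s'", color_by)
  }
  v <- fetch_gene(bundle$store, color_by)
  d <- discretize_expression(v, n_bins = bundle$manifest$bins)
  leg <- assign_colors(d$legend, palette %||% bundle$manifest$palettes$expression)
  legend <- data.frame(label = legend_bin_labels(leg), color = leg$bin_colors,
                       count = leg$bin_counts, stringsAsFactors = FALSE)
  list(kind = "gene", name = color_by, point_colors = leg$bin_colors[d$bin + 1L],
       legend = legend)
}

legend_bin_labels <- function(leg) {
  if (leg$n_bins == 1L) return("all")
  n_pos <- leg$n_bins - as.integer(leg$zero_bin)
  b <- leg$breaks
  pos <- sprintf("(%.3g-%.3g]", b[seq_len(n_pos)], b[seq_len(n_pos) + 1L])
  if (leg$zero_bin) c("0", pos) else pos
}

get_layout <- function(bundle, layout_name) {
  for (ly in bundle$layouts) if (ly$name == layout_name) return(ly)
  sb_stop("unknown layout '%s'; available: %s", layout_name,
          paste(vapply(bundle$layouts, `[[`, "", "name"), collapse = ", "))
}

draw_scatter_pane <- function(ly, colors, selection_idx, point_size, main,
                              xlim, ylim) {
  graphics::plot(ly$x, ly$y, col = colors, pch = 16, cex = point_size,
                 xlab = paste0(ly$name, "_1"), ylab = paste0(ly$name, "_2"),
                 main = main, xlim = xlim, ylim = ylim, asp = 1)
  if (any(selection_idx))
    graphics::points(ly$x[selection_idx], ly$y[selection_idx], pch = 1,
                     cex = point_size * 1.6, col = "black", lwd = 1.2)
}

scatter_pane_report <- function(bundle, layout_name, color_by, palette,
                                selection) {
  ly <- get_layout(bundle, layout_name)
  src <- resolve_colors(bundle, color_by, palette)
  sel_idx <- ly$cell_ids %in% (selection %||% character(0))
  per_color <- table(src$point_colors)
  list(layout = layout_name,
       color_source = list(kind = src$kind, name = src$name),
       n_points = length(ly$x),
       x_range = range(ly$x), y_range = range(ly$y),
       selection_count = sum(sel_idx),
       legend = lapply(seq_len(nrow(src$legend)), function(i)
         as.list(src$legend[i, ])),
       per_color_counts = as.list(setNames(as.integer(per_color),
                                           names(per_color))),
       src = src, ly = ly, sel_idx = sel_idx)
}

strip_internals <- function(rep) {
  rep$src <- NULL; rep$ly <- NULL; rep$sel_idx <- NULL
  rep
}

#' Render a scatter plot of a layout colored by metadata or a gene
#'
#' The primary display: one point per cell at its embedding coordinates,
#' colored by a categorical field's color map or by an expression legend
#' (zero bin lightest, highest bin darkest). Selected cells are outlined
#' in black. The render report carries the per-legend-entry counts, axis
#' ranges and selection count.
#'
#' @param bundle An `sb_bundle`.
#' @param layout_name Layout to draw.
#' @param color_by Metadata field name or gene id.
#' @param out Output figure path (`.svg` or `.png`); the report is written
#'   to `<out>.report.json`.
#' @param palette Optional palette override.
#' @param selection Optional cell ids to outline.
#' @param point_size Point size (cex units).
#' @param width,height Figure size in pixels.
#' @return The render report, invisibly.
#' @export
render_scatter <- function(bundle, layout_name, color_by, out,
                           palette = NULL, selection = NULL,
                           point_size = 0.6, width = 800, height = 600) {
  rep <- scatter_pane_report(bundle, layout_name, color_by, palette, selection)
  open_device(out, width, height)
  draw_scatter_pane(rep$ly, rep$src$point_colors, rep$sel_idx, point_size,
                    sprintf("%s: %s", bundle$manifest$short_label, color_by),
                    xlim = rep$x_range, ylim = rep$y_range)
  grDevices::dev.off()
  rep <- c(list(type = "scatter", figure = out), strip_internals(rep))
  invisible(write_report(rep, out))
}

#' Render a side-by-side split scatter
#'
#' Two panes over the same layout (a field next to a gene, two genes, ...)
#' share identical axis ranges so point positions correspond; each pane
#' carries its own legend in the report.
#'
#' @param bundle An `sb_bundle`.
#' @param layout_name Shared layout.
#' @param color_left,color_right Color source per pane (field or gene).
#' @param out Output figure path.
#' @param palette Optional palette override for both panes.
#' @param selection Optional cell ids outlined in both panes.
#' @param point_size,width,height As [render_scatter()].
#' @return The render report (with `panes$left` / `panes$right`), invisibly.
#' @export
render_split <- function(bundle, layout_name, color_left, color_right, out,
                         palette = NULL, selection = NULL, point_size = 0.6,
                         width = 1200, height = 600) {
  left <- scatter_pane_report(bundle, layout_name, color_left, palette, selection)
  right <- scatter_pane_report(bundle, layout_name, color_right, palette, selection)
  xlim <- range(left$x_range, right$x_range)
  ylim <- range(left$y_range, right$y_range)
  left$x_range <- right$x_range <- xlim
  left$y_range <- right$y_range <- ylim
  open_device(out, width, height)
  graphics::par(mfrow = c(1, 2))
  draw_scatter_pane(left$ly, left$src$point_colors, left$sel_idx, point_size,
                    color_left, xlim, ylim)
  draw_scatter_pane(right$ly, right$src$point_colors, right$sel_idx, point_size,
                    color_right, xlim, ylim)
  grDevices::dev.off()
  rep <- list(type = "split", figure = out,
              layout = layout_name, x_range = xlim, y_range = ylim,
              panes = list(left = strip_internals(left),
                           right = strip_internals(right)))
  invisible(write_report(rep, out))
}

#' Render a violin comparison figure
#'
#' Two mirrored density outlines (selection vs background) with quartile
#' marks at exactly the comparison's statistics; group sizes go into the
#' axis labels. A single-cell group degenerates to a stick mark.
#'
#' @param comparison An `sb_violin` from [violin_stats()].
#' @param out Output figure path.
#' @param width,height Figure size in pixels.
#' @return The render report, invisibly.
#' @export
render_violin <- function(comparison, out, width = 500, height = 500) {
  stopifnot(inherits(comparison, "sb_violin"))
  groups <- list(selection = comparison$group_a,
                 background = comparison$group_b)
  open_device(out, width, height)
  all_v <- c(groups[[1L]]$values, groups[[2L]]$values)
  graphics::plot(NULL, xlim = c(0.5, 2.5), ylim = range(all_v),
                 xaxt = "n", xlab = "", ylab = comparison$gene_id)
  graphics::axis(1, at = 1:2, labels = sprintf("%s (n=%d)", names(groups),
                 vapply(groups, `[[`, 1L, "cell_count")))
  for (i in 1:2) {
    gr <- groups[[i]]
    if (gr$cell_count > 1L && length(unique(gr$values)) > 1L) {
      d <- stats::density(gr$values)
      w <- d$y / max(d$y) * 0.4
      graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                        col = "#9ECAE1", border = "#3182BD")
    } else {
      graphics::segments(i - 0.2, gr$values[1L], i + 0.2, gr$values[1L],
                         lwd = 2)
    }
    graphics::segments(i - 0.25, c(gr$q1, gr$median, gr$q3),
                       i + 0.25, c(gr$q1, gr$median, gr$q3),
                       lwd = c(1, 2, 1))
  }
  grDevices::dev.off()
  stats_of <- function(gr) gr[c("cell_count", "mean", "median", "q1", "q3",
                                "min", "max")]
  rep <- list(type = "violin", figure = out, gene = comparison$gene_id,
              groups = list(selection = stats_of(groups$selection),
                            background = stats_of(groups$background)),
              log = as.list(comparison$log))
  invisible(write_report(rep, out))
}

#' Render a cluster-by-gene heatmap figure
#'
#' Clusters on the y axis, genes on the x axis, tile color from the
#' per-gene 0-1 scaled mean (computed here when the input is unscaled).
#' The report carries labels and the exact tile values.
#'
#' @param hm An `sb_heatmap` from [cluster_means()].
#' @param out Output figure path.
#' @param palette Sequential palette for tiles.
#' @param width,height Figure size in pixels.
#' @return The render report, invisibly.
#' @export
render_heatmap <- function(hm, out, palette = "whiteRed",
                           width = 800, height = 400) {
  stopifnot(inherits(hm, "sb_heatmap"))
  if (length(hm$gene_ids) == 0L) sb_stop("heatmap has no genes")
  m <- hm$matrix
  if (hm$scaling == "none") {
    m <- apply(m, 2L, function(col) {
      rng <- range(col)
      if (rng[2L] > rng[1L]) (col - rng[1L]) / (rng[2L] - rng[1L])
      else rep(0, length(col))
    })
    m <- matrix(m, nrow = length(hm$cluster_labels),
                dimnames = dimnames(hm$matrix))
  }
  cols <- ramp_colors(get_palette(palette), 100L)
  open_device(out, width, height)
  graphics::par(mar = c(6, 8, 2, 2))
  graphics::image(x = seq_along(hm$gene_ids), y = seq_along(hm$cluster_labels),
                  z = t(m)[, rev(seq_along(hm$cluster_labels)), drop = FALSE],
                  col = cols, zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_along(hm$gene_ids), labels = hm$gene_ids,
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(hm$cluster_labels),
                 labels = rev(hm$cluster_labels), las = 1, cex.axis = 0.8)
  grDevices::dev.off()
  rep <- list(type = "heatmap", figure = out,
              cluster_labels = hm$cluster_labels, gene_ids = hm$gene_ids,
              summary = hm$summary, scaling = "per-gene",
              values = lapply(seq_along(hm$cluster_labels), function(i)
                unname(m[i, ])),
              raw_values = lapply(seq_along(hm$cluster_labels), function(i)
                unname(hm$matrix[i, ])))
  invisible(write_report(rep, out))
}
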