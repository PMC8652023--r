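#' Classify a raw metadata column into a typed field
#'
#' A column is `numeric` if every non-missing value parses as a number,
#' `uniqueId` if all values are distinct and non-numeric, and `categorical`
#' otherwise. Missing markers (`""`, `"NA"`, `"NaN"`) never influence the
#' classification: for numeric fields they become `NA`, for categorical
#' fields they form their own `"(missing)"` category (colored gray by
#' [assign_colors()]) so they stay visible rather than silently dropped.
#'
#' Categorical values are coded `0..K-1` in descending count order, ties
#' broken lexicographically, which keeps legends stable across runs.
#'
#' @param name Field name.
#' @param raw_values Character vector, one value per cell.
#' @return An `sb_field` with `name`, `kind`, `values` (codes for
#'   categorical, numbers for numeric, strings for uniqueId), `value_dict`,
#'   `counts` and an empty `color_map`.
#' @export
infer_field_kind <- function(name, raw_values) {
  raw_values <- as.character(raw_values)
  if (length(raw_values) == 0L) sb_stop("field '%s' has no values", name)
  miss <- is_missing_marker(raw_values)
  nums <- suppressWarnings(as.numeric(raw_values[!miss]))
  if (length(nums) && !anyNA(nums)) {
    values <- rep(NA_real_, length(raw_values))
    values[!miss] <- nums
    return(structure(list(name = name, kind = "numeric", values = values,
                          value_dict = NULL, counts = NULL,
                          n_missing = sum(miss), color_map = NULL),
                     class = "sb_field"))
  }
  if (!any(miss) && !anyDuplicated(raw_values)) {
    return(structure(list(name = name, kind = "uniqueId", values = raw_values,
                          value_dict = NULL, counts = NULL,
                          n_missing = 0L, color_map = NULL),
                     class = "sb_field"))
  }
  shown <- ifelse(miss, "(missing)", raw_values)
  tab <- table(shown)
  ord <- order(-as.integer(tab), names(tab))
  levels <- names(tab)[ord]
  value_dict <- setNames(seq_along(levels) - 1L, levels)
  structure(list(name = name, kind = "categorical",
                 values = unname(value_dict[shown]),
                 value_dict = value_dict,
                 counts = setNames(as.integer(tab)[ord], levels),
                 n_missing = sum(miss), color_map = NULL),
            class = "sb_field")
}

# decoded (display) values for any field kind
decode_field <- function(field) {
  switch(field$kind,
    categorical = names(field$value_dict)[field$values + 1L],
    numeric = field$values,
    uniqueId = field$values)
}

# subset/reorder a typed field by cell index
reindex_field <- function(field, idx) {
  f <- field
  f$values <- field$values[idx]
  if (field$kind == "categorical") {
    # recount over the kept cells; dictionary order is preserved
    lev <- names(field$value_dict)
    tab <- table(factor(lev[f$values + 1L], levels = lev))
    f$counts <- setNames(as.integer(tab), lev)
  }
  f
}

#' Discretize an expression vector into ordered color bins
#'
#' Single-cell expression vectors are zero-inflated, so when zeros are
#' present bin 0 is reserved for exact zeros and the remaining bins
#' partition the positive values, either by quantiles of the positive
#' values (default) or into equal-width intervals. Quantile breaks that
#' collide (heavy ties) are deduplicated; if fewer distinct breaks remain
#' the bin count shrinks and the shrink is logged. An all-equal vector
#' yields a single-bin legend with a logged warning.
#'
#' @param vector Non-negative finite numeric vector (one value per cell).
#' @param n_bins Total number of bins requested (including the zero bin
#'   when zeros exist); must be >= 2.
#' @param strategy `"quantile"` (default) or `"linear"`.
#' @return A list with `legend` (an `sb_legend`: `breaks`, `n_bins`,
#'   `bin_colors` — unset until [assign_colors()] —, `bin_counts`,
#'   `zero_bin`, `log`) and `bin` (per-cell 0-based bin index).
#' @export
discretize_expression <- function(vector, n_bins = 10L,
                                  strategy = c("quantile", "linear")) {
  strategy <- match.arg(strategy)
  if (n_bins < 2L) sb_stop("n_bins must be >= 2, got %d", n_bins)
  if (!all(is.finite(vector))) sb_stop("expression vector has non-finite values")
  if (any(vector < 0)) sb_stop("expression vector has negative values")
  n <- length(vector)
  log <- character()

  zero_bin <- any(vector == 0)
  pos <- vector[vector > 0]

  if (length(unique(vector)) == 1L) {
    log <- sb_log(log, "constant expression vector: single-bin legend")
    legend <- structure(list(breaks = unique(range(vector)), n_bins = 1L,
                             bin_colors = NULL, bin_counts = n,
                             zero_bin = zero_bin && vector[1L] == 0, log = log),
                        class = "sb_legend")
    return(list(legend = legend, bin = rep(0L, n)))
  }

  n_pos_bins <- if (zero_bin) n_bins - 1L else n_bins
  if (strategy == "quantile") {
    breaks <- unname(quantile(pos, probs = seq(0, 1, length.out = n_pos_bins + 1L),
                              type = 7))
  } else {
    breaks <- seq(min(pos), max(pos), length.out = n_pos_bins + 1L)
  }
  breaks <- unique(breaks)
  if (length(breaks) - 1L < n_pos_bins) {
    # heavy ties collapsed some quantiles; at least one positive bin remains
    shrunk <- max(1L, length(breaks) - 1L)
    if (shrunk < n_pos_bins)
      log <- sb_log(log, "tied breaks: positive bins shrunk from %d to %d",
                    n_pos_bins, shrunk)
    n_pos_bins <- shrunk
  }

  # positive value v falls in bin j when breaks[j] < v <= breaks[j+1],
  # with the minimum closed on the left
  pos_bin <- findInterval(vector, breaks, rightmost.closed = TRUE,
                          left.open = TRUE)
  pos_bin[vector == breaks[1L]] <- 1L
  pos_bin <- pmin(pmax(pos_bin, 1L), n_pos_bins)
  bin <- integer(n)
  if (zero_bin) {
    bin[vector == 0] <- 0L
    bin[vector > 0] <- pos_bin[vector > 0L] # 1..n_pos_bins
  } else {
    bin <- pos_bin - 1L
  }
  total_bins <- n_pos_bins + as.integer(zero_bin)
  bin_counts <- as.integer(table(factor(bin, levels = 0:(total_bins - 1L))))
  legend <- structure(list(breaks = breaks, n_bins = total_bins,
                           bin_colors = NULL, bin_counts = bin_counts,
                           zero_bin = zero_bin, log = log),
                      class = "sb_legend")
  list(legend = legend, bin = bin)
}

#' Assign palette colors to a field or expression legend
#'
#' Categorical fields cycle through a qualitative palette in code order;
#' the `"(missing)"` category always gets a fixed gray. Expression legends
#' sample a sequential ramp evenly so the highest bin receives the ramp's
#' darkest endpoint.
#'
#' @param x An `sb_field` (categorical) or `sb_legend`.
#' @param palette_name One of `names(BUILTIN_PALETTES)`.
#' @return `x` with `color_map` (field) or `bin_colors` (legend) filled in.
#' @export
assign_colors <- function(x, palette_name) {
  pal <- get_palette(palette_name)
  if (inherits(x, "sb_field")) {
    if (x$kind != "categorical")
      sb_stop("can only color categorical fields; '%s' is %s", x$name, x$kind)
    if (attr(pal, "type") != "qualitative")
      sb_stop("palette '%s' is sequential; categorical fields need a qualitative palette",
              palette_name)
    lev <- names(x$value_dict)
    cols <- pal[(seq_along(lev) - 1L) %% length(pal) + 1L]
    cols[lev == "(missing)"] <- MISSING_COLOR
    x$color_map <- setNames(unname(cols), lev)
  } else if (inherits(x, "sb_legend")) {
    if (attr(pal, "type") != "sequential")
      sb_stop("palette '%s' is qualitative; expression legends need a sequential ramp",
              palette_name)
    x$bin_colors <- ramp_colors(pal, x$n_bins)
  } else {
    sb_stop("assign_colors expects an sb_field or sb_legend")
  }
  x
}

#' Histogram of a metadata field over a cell subset
#'
#' Counts per category (categorical/uniqueId fields count decoded values)
#' or per bin of a freshly computed legend (numeric fields), restricted to
#' a subset of cells. Counts always sum to the subset size; an empty subset
#' gives an all-zero histogram.
#'
#' @param field An `sb_field`.
#' @param cell_ids Canonical cell ids the field's values are aligned to.
#' @param subset Cell ids to tally (subset of `cell_ids`).
#' @param n_bins Bins for numeric fields.
#' @return Named integer vector of counts.
#' @export
field_histogram <- function(field, cell_ids, subset = cell_ids, n_bins = 10L) {
  unknown <- setdiff(subset, cell_ids)
  if (length(unknown))
    sb_stop("subset contains %d unknown cells (e.g. '%s')",
            length(unknown), unknown[1L])
  keep <- cell_ids %in% subset
  if (field$kind == "categorical") {
    lev <- names(field$value_dict)
    vals <- factor(lev[field$values[keep] + 1L], levels = lev)
    return(setNames(as.integer(table(vals)), lev))
  }
  if (field$kind == "uniqueId") {
    vals <- field$values[keep]
    return(setNames(as.integer(table(factor(vals, levels = sort(unique(field$values))))),
                    sort(unique(field$values))))
  }
  v <- field$values[!is.na(field$values)]
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  if (edges[1L] == edges[length(edges)]) edges <- c(edges[1L], edges[1L])
  sub <- field$values[keep]
  sub <- sub[!is.na(sub)]
  b <- findInterval(sub, edges, rightmost.closed = TRUE, left.open = TRUE)
  b[sub == edges[1L]] <- 1L
  nb <- length(edges) - 1L
  labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1L],
                    c(rep(")", nb - 1L), "]"))
  setNames(as.integer(table(factor(b, levels = seq_len(nb)))), labels)
}
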