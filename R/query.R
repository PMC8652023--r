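#' Build a cell-selection query
#'
#' A selection query is a conjunction of predicates over metadata fields,
#' the headless form of interactively combining one or more metadata
#' filters. Supported operators: `equals`, `in` (set membership), `range`
#' (closed interval `[low, high]`), `greater` (strict) and `less` (strict).
#' Categorical predicates compare decoded values; numeric predicates
#' compare parsed numbers, and applying them to a categorical field is an
#' error rather than a silent coercion.
#'
#' @param ... Predicates created with [pred()].
#' @return An `sb_query`.
#' @export
sb_query <- function(...) {
  preds <- list(...)
  for (p in preds) {
    if (!inherits(p, "sb_pred")) sb_stop("sb_query() takes pred() predicates")
  }
  structure(list(predicates = preds, combinator = "and"), class = "sb_query")
}

#' @rdname sb_query
#' @param field Metadata field name.
#' @param op One of `"equals"`, `"in"`, `"range"`, `"greater"`, `"less"`.
#' @param value Operand: a single value, a set for `"in"`, or `c(low, high)`
#'   with `low <= high` for `"range"`.
#' @export
pred <- function(field, op = c("equals", "in", "range", "greater", "less"),
                 value) {
  op <- match.arg(op)
  if (op == "range") {
    value <- as.numeric(value)
    if (length(value) != 2L || anyNA(value) || value[1L] > value[2L])
      sb_stop("range operand must be c(low, high) with low <= high")
  }
  structure(list(field = field, op = op, value = value), class = "sb_pred")
}

# evaluate one predicate against a typed field -> logical per cell
eval_pred <- function(p, field) {
  numeric_ops <- c("range", "greater", "less")
  if (p$op %in% numeric_ops && field$kind != "numeric")
    sb_stop("operator '%s' needs a numeric field; '%s' is %s",
            p$op, p$field, field$kind)
  if (field$kind == "numeric") {
    v <- field$values
    switch(p$op,
      equals  = !is.na(v) & v == as.numeric(p$value),
      `in`    = !is.na(v) & v %in% as.numeric(p$value),
      range   = !is.na(v) & v >= p$value[1L] & v <= p$value[2L],
      greater = !is.na(v) & v > as.numeric(p$value),
      less    = !is.na(v) & v < as.numeric(p$value))
  } else {
    v <- decode_field(field)
    switch(p$op,
      equals = v == as.character(p$value),
      `in`   = v %in% as.character(p$value))
  }
}

#' Select cells matching a query
#'
#' @param cells An [sb_cells] table with typed fields.
#' @param q An [sb_query]. An empty predicate list selects all cells
#'   (vacuous conjunction).
#' @return Character vector of matching cell ids, in canonical order.
#' @export
select_cells <- function(cells, q) {
  stopifnot(inherits(cells, "sb_cells"), inherits(q, "sb_query"))
  keep <- rep(TRUE, length(cells$cell_ids))
  for (p in q$predicates) {
    field <- cells$fields[[p$field]]
    if (is.null(field))
      sb_stop("unknown field '%s'; available: %s", p$field,
              paste(names(cells$fields), collapse = ", "))
    if (!inherits(field, "sb_field"))
      sb_stop("field '%s' is untyped; run infer_field_kind first", p$field)
    keep <- keep & eval_pred(p, field)
  }
  cells$cell_ids[keep]
}

#' Export cell identifiers to a plain-text file
#'
#' Writes one cell id per line (LF endings) in canonical order, the format
#' other tools ingest for downstream analyses of a selection.
#'
#' @param selection Cell ids to export (subset of `cell_ids`).
#' @param cell_ids Canonical cell order.
#' @param out_path Output file.
#' @return Number of lines written, invisibly returned as a count.
#' @export
export_cells <- function(selection, cell_ids, out_path) {
  unknown <- setdiff(selection, cell_ids)
  if (length(unknown))
    sb_stop("selection contains %d unknown cells (e.g. '%s')",
            length(unknown), unknown[1L])
  ordered <- cell_ids[cell_ids %in% selection]
  con <- file(out_path, "wb")
  on.exit(close(con))
  if (length(ordered)) writeLines(ordered, con, sep = "\n")
  length(ordered)
}

# five-number-plus summary used by the violin comparison; quartiles use
# linear interpolation (quantile type 7), pinned for reproducibility
group_stats <- function(values) {
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(cell_count = length(values), mean = mean(values), median = q[2L],
       q1 = q[1L], q3 = q[3L], min = min(values), max = max(values),
       values = values)
}

#' Violin comparison of a gene between a selection and its background
#'
#' Computes the distribution summaries behind a violin plot: the gene's
#' expression in the selected cells versus either a user-given background
#' set or, by default, all other cells in the dataset. If the background
#' overlaps the selection, the overlap is removed from the background (a
#' background is a loose set in practice) and the removal is logged on the
#' result.
#'
#' @param store An `sb_store`.
#' @param gene_id Gene symbol or alias.
#' @param selection Nonempty cell id set.
#' @param cell_ids Canonical cell order (defines "all other cells").
#' @param background Optional cell id set; `NULL` means the rest.
#' @return An `sb_violin` with `gene_id`, `group_a`, `group_b` (each the
#'   output of the summary: cell_count, mean, median, q1, q3, min, max,
#'   values) and `log`.
#' @export
violin_stats <- function(store, gene_id, selection, cell_ids,
                         background = NULL) {
  if (length(selection) == 0L) sb_stop("selection is empty")
  unknown <- setdiff(selection, cell_ids)
  if (length(unknown))
    sb_stop("selection contains %d unknown cells (e.g. '%s')",
            length(unknown), unknown[1L])
  log <- character()
  if (is.null(background)) {
    bg <- setdiff(cell_ids, selection)
  } else {
    overlap <- intersect(background, selection)
    if (length(overlap)) {
      log <- sb_log(log, "removed %d cells from background (overlap with selection)",
                    length(overlap))
    }
    bg <- setdiff(background, selection)
  }
  if (length(bg) == 0L)
    sb_stop("background group is empty (after overlap removal)")
  v <- fetch_gene(store, gene_id)
  sel_idx <- cell_ids %in% selection
  bg_idx <- cell_ids %in% bg
  structure(list(gene_id = gene_id,
                 group_a = group_stats(v[sel_idx]),
                 group_b = group_stats(v[bg_idx]),
                 log = log),
            class = "sb_violin")
}

#' Per-cluster mean expression of a gene list
#'
#' The table behind the heatmap view: entry (cluster, gene) is the mean
#' expression of that gene over the cluster's cells. Genes not found in the
#' store are skipped with a warning (a curated list may mention genes the
#' matrix lacks). Optional per-gene scaling maps each gene's row of means
#' to `(v - min) / (max - min)`; a constant row scales to all zeros.
#'
#' @param store An `sb_store`.
#' @param cluster_field Categorical `sb_field` aligned to `cell_ids`.
#' @param cell_ids Canonical cell order.
#' @param genes Ordered gene list (typically the dataset genes).
#' @param scaling `"none"` or `"per-gene"`.
#' @return An `sb_heatmap` with `cluster_labels`, `gene_ids`, `matrix`
#'   (clusters x genes), `summary = "mean"`, `scaling`.
#' @export
cluster_means <- function(store, cluster_field, cell_ids, genes,
                          scaling = c("none", "per-gene")) {
  scaling <- match.arg(scaling)
  if (!inherits(cluster_field, "sb_field") || cluster_field$kind != "categorical")
    sb_stop("cluster field must be categorical, got %s",
            if (inherits(cluster_field, "sb_field")) cluster_field$kind else class(cluster_field)[1L])
  if (length(cluster_field$values) != length(cell_ids))
    sb_stop("cluster field covers %d cells, canonical order has %d",
            length(cluster_field$values), length(cell_ids))
  labels <- names(cluster_field$value_dict)
  fac <- factor(labels[cluster_field$values + 1L], levels = labels)
  kept <- character(0)
  rows <- list()
  for (g in genes) {
    v <- tryCatch(fetch_gene(store, g), error = function(e) NULL)
    if (is.null(v)) {
      sb_warn("gene '%s' not in store; skipped from heatmap", g)
      next
    }
    mu <- vapply(split(v, fac), mean, numeric(1L))
    if (scaling == "per-gene") {
      rng <- range(mu)
      mu <- if (rng[2L] > rng[1L]) (mu - rng[1L]) / (rng[2L] - rng[1L])
            else rep(0, length(mu))
    }
    kept <- c(kept, g)
    rows[[g]] <- mu
  }
  mat <- if (length(kept)) do.call(cbind, rows)
         else matrix(numeric(0), nrow = length(labels), ncol = 0L)
  dimnames(mat) <- list(labels, kept)
  structure(list(cluster_labels = labels, gene_ids = kept, matrix = mat,
                 summary = "mean", scaling = scaling),
            class = "sb_heatmap")
}

#' Write a heatmap table as TSV (clusters x genes)
#'
#' @param hm An `sb_heatmap`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path) {
  dt <- data.table::data.table(cluster = hm$cluster_labels)
  for (g in hm$gene_ids) dt[[g]] <- hm$matrix[, g]
  con <- file(path, "wb")
  lines <- c(paste(names(dt), collapse = "\t"),
             do.call(paste, c(lapply(dt, function(x)
               if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
               else as.character(x)), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
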