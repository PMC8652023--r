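#' In-memory expression matrix
#'
#' The canonical gene-by-cell container every importer produces. Values may
#' be a base dense matrix or a sparse [Matrix::dgCMatrix-class]; genes are
#' rows, cells are columns. Duplicate gene identifiers are deduplicated by
#' suffixing `_2`, `_3`, ... in input order (never summed), so every input
#' row stays retrievable; the renames are recorded in the build log.
#'
#' @param gene_ids Character vector of gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @param values Numeric gene x cell matrix (dense or sparse), all values
#'   finite and >= 0. Negative values are rejected, not clamped.
#' @param aliases Optional named character vector mapping alias ids
#'   (e.g. accessions) to display gene ids.
#' @param log Character vector of build-log lines to extend.
#' @return An `sb_matrix` object.
#' @export
sb_matrix <- function(gene_ids, cell_ids, values, aliases = NULL,
                      log = character()) {
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    sb_stop("matrix has %d rows but %d gene ids", nrow(values), length(gene_ids))
  if (ncol(values) != length(cell_ids))
    sb_stop("matrix has %d columns but %d cell ids", ncol(values), length(cell_ids))
  if (anyDuplicated(cell_ids))
    sb_stop("duplicate cell id: '%s'", cell_ids[duplicated(cell_ids)][1L])
  if (length(values)) {
    rng <- suppressWarnings(range(values))
    if (!all(is.finite(rng)))
      sb_stop("matrix contains non-finite values")
    if (rng[1L] < 0)
      sb_stop("matrix contains negative values (min %g); expression values must be >= 0",
              rng[1L])
  }
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    tab <- new.env(parent = emptyenv())
    gene_ids <- vapply(gene_ids, function(g) {
      k <- get0(g, envir = tab, ifnotfound = 0L) + 1L
      assign(g, k, envir = tab)
      if (k == 1L) g else paste0(g, "_", k)
    }, character(1L), USE.NAMES = FALSE)
    log <- sb_log(log, "deduplicated %d duplicate gene ids by suffixing", sum(dup))
  }
  if (!is.null(aliases)) {
    aliases <- aliases[!is.na(names(aliases)) & names(aliases) != ""]
    aliases <- aliases[!duplicated(names(aliases))]
  }
  structure(list(gene_ids = gene_ids, cell_ids = cell_ids, values = values,
                 aliases = aliases, log = log),
            class = "sb_matrix")
}

#' @export
dim.sb_matrix <- function(x) c(length(x$gene_ids), length(x$cell_ids))

#' @export
print.sb_matrix <- function(x, ...) {
  cat(sprintf("<sb_matrix> %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

# one gene's vector across all cells, as base numeric
matrix_row <- function(em, i) {
  v <- em$values[i, ]
  as.numeric(v)
}

# resolve a gene id or alias to a row index; NA if unknown
resolve_gene <- function(em, gene_id) {
  i <- match(gene_id, em$gene_ids)
  if (is.na(i) && !is.null(em$aliases)) {
    hit <- em$aliases[match(gene_id, names(em$aliases))]
    if (!is.na(hit)) i <- match(unname(hit), em$gene_ids)
  }
  i
}

#' Read a MatrixMarket sparse matrix with features/barcodes sidecars
#'
#' Reads the Cellranger-style triple: a coordinate-format `.mtx` file plus a
#' features file (gene ids, one per row) and barcodes file (cell ids, one
#' per row). All three may be gzipped. When the features file has two or
#' more columns, column 2 (the symbol) becomes the display gene id and
#' column 1 (the accession) is kept as an alias, matching what users type in
#' a gene search; a single-column file uses column 1 directly.
#'
#' @param matrix_path Path to the `.mtx` / `.mtx.gz` coordinate file.
#' @param features_path Path to features/genes TSV (1+ columns, no header).
#' @param barcodes_path Path to barcodes TSV (one cell id per row, no header).
#' @return An [sb_matrix] (sparse-backed); coordinates absent from the file
#'   are zero.
#' @export
read_matrix_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feat <- sb_fread(features_path, header = FALSE, sep = "\t",
                            colClasses = "character")
  bc <- sb_fread(barcodes_path, header = FALSE, sep = "\t",
                          colClasses = "character")[[1L]]
  if (nrow(feat) != nrow(m))
    sb_stop("matrix header declares %d genes but features file has %d rows",
            nrow(m), nrow(feat))
  if (length(bc) != ncol(m))
    sb_stop("matrix header declares %d cells but barcodes file has %d rows",
            ncol(m), length(bc))
  if (length(m@x) && min(m@x) < 0)
    sb_stop("MTX file contains negative values")
  if (ncol(feat) >= 2L) {
    gene_ids <- feat[[2L]]
    aliases <- setNames(gene_ids, feat[[1L]])
  } else {
    gene_ids <- feat[[1L]]
    aliases <- NULL
  }
  sb_matrix(gene_ids, bc, methods::as(m, "CsparseMatrix"), aliases = aliases)
}

#' Read a dense TSV/CSV expression matrix
#'
#' Expects one header row of cell ids and one leading gene-id column (or the
#' transpose, with `genes_in = "columns"`). The delimiter is taken from the
#' header line: tab if it contains any tab, else comma.
#'
#' @param path Dense text matrix, optionally gzipped.
#' @param genes_in `"rows"` (default) if rows are genes, `"columns"` if the
#'   file is transposed (rows are cells).
#' @return An [sb_matrix] (dense).
#' @export
read_matrix_dense <- function(path, genes_in = c("rows", "columns")) {
  genes_in <- match.arg(genes_in)
  delim <- detect_delim(first_line(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  if (length(lines) < 2L) sb_stop("dense matrix '%s' has no data rows", path)
  parts <- strsplit(lines, delim, fixed = TRUE)
  ncols <- length(parts[[1L]])
  bad <- which(lengths(parts) != ncols)
  if (length(bad))
    sb_stop("ragged row in '%s': line %d has %d fields, header has %d",
            path, bad[1L], length(parts[[bad[1L]]]), ncols)
  header <- parts[[1L]]
  body <- parts[-1L]
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  col_ids <- header[-1L]
  vals <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1L]), numeric(ncols - 1L)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    sb_stop("non-numeric value in '%s' at data row %d, column %d",
            path, idx[2L], idx[1L] + 1L)
  }
  # vapply returned cells x genes; transpose to genes x cells
  vals <- if (ncols - 1L == 1L) matrix(vals, ncol = length(body)) else t(vals)
  if (genes_in == "rows") {
    sb_matrix(row_ids, col_ids, vals)
  } else {
    sb_matrix(col_ids, row_ids, t(vals))
  }
}

#' Cell metadata table
#'
#' Holds one row per cell. Fields are stored raw (as text) until typed by
#' [infer_field_kind()]; the first field is always the cell identifier
#' itself (kind `uniqueId`).
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param fields Named list of per-cell vectors (one value per cell).
#' @param log Build-log lines to carry forward.
#' @return An `sb_cells` object.
#' @export
sb_cells <- function(cell_ids, fields = list(), log = character()) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids))
    sb_stop("duplicate cell id in metadata: '%s'",
            cell_ids[duplicated(cell_ids)][1L])
  for (nm in names(fields)) {
    v <- fields[[nm]]
    nv <- if (inherits(v, "sb_field")) length(v$values) else length(v)
    if (nv != length(cell_ids))
      sb_stop("field '%s' has %d values for %d cells", nm, nv, length(cell_ids))
  }
  structure(list(cell_ids = cell_ids, fields = fields, log = log),
            class = "sb_cells")
}

#' Read a cell metadata table
#'
#' TSV or CSV with a header row; the first column is the cell identifier.
#' Fields are kept untyped (text); call [infer_field_kind()] (done during
#' the bundle build) to classify them.
#'
#' @param path Metadata table, optionally gzipped.
#' @return An [sb_cells] table.
#' @export
read_annotations <- function(path) {
  delim <- detect_delim(first_line(path))
  dt <- sb_fread(path, sep = delim, header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (nrow(dt) == 0L) sb_stop("metadata file '%s' is empty", path)
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    sb_stop("duplicate cell id in '%s': '%s'", path, ids[duplicated(ids)][1L])
  fields <- as.list(dt[, -1L, drop = FALSE])
  sb_cells(ids, fields)
}

#' 2D layout (embedding) coordinates
#'
#' @param name Layout label shown to users (e.g. `"tSNE"`, `"UMAP"`).
#' @param cell_ids Cells with coordinates.
#' @param x,y Finite coordinates, one per cell.
#' @param n_dropped Count of input rows dropped for non-finite coordinates.
#' @return An `sb_layout` object.
#' @export
sb_layout <- function(name, cell_ids, x, y, n_dropped = 0L) {
  stopifnot(length(cell_ids) == length(x), length(x) == length(y))
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    sb_stop("layout '%s' contains non-finite coordinates", name)
  structure(list(name = name, cell_ids = as.character(cell_ids),
                 x = as.numeric(x), y = as.numeric(y),
                 n_dropped = as.integer(n_dropped)),
            class = "sb_layout")
}

#' Read a layout coordinate table
#'
#' TSV/CSV with columns cell, x, y (header row required). Rows whose x or y
#' does not parse to a finite number are dropped and counted; the count is
#' carried on the returned layout and surfaces in the build log.
#'
#' @param path Coordinate table, optionally gzipped.
#' @param name Layout label.
#' @return An [sb_layout].
#' @export
read_layout <- function(path, name) {
  delim <- detect_delim(first_line(path))
  dt <- sb_fread(path, sep = delim, header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 3L)
    sb_stop("layout file '%s' has %d columns; need cell, x, y", path, ncol(dt))
  x <- suppressWarnings(as.numeric(dt[[2L]]))
  y <- suppressWarnings(as.numeric(dt[[3L]]))
  keep <- is.finite(x) & is.finite(y)
  sb_layout(name, dt[[1L]][keep], x[keep], y[keep],
            n_dropped = sum(!keep))
}

#' Align matrix, metadata and layouts into a canonical dataset
#'
#' Restricts all three sources to their common cells and reorders everything
#' to the canonical order: the matrix column order restricted to the
#' intersection. Counts of cells dropped from each source are appended to
#' the build log. Alignment is idempotent.
#'
#' @param matrix An [sb_matrix].
#' @param cells An [sb_cells] table.
#' @param layouts List of [sb_layout]s (at least one).
#' @param dataset_genes Optional curated gene list; unresolvable entries are
#'   dropped with a log line.
#' @return An `sb_dataset` with components `matrix`, `cells`, `layouts`,
#'   `dataset_genes` and `log`.
#' @export
align_cells <- function(matrix, cells, layouts, dataset_genes = character()) {
  stopifnot(inherits(matrix, "sb_matrix"), inherits(cells, "sb_cells"))
  if (length(layouts) == 0L) sb_stop("dataset needs at least one layout")
  log <- c(matrix$log, cells$log)
  common <- matrix$cell_ids[matrix$cell_ids %in% cells$cell_ids]
  for (ly in layouts) common <- common[common %in% ly$cell_ids]
  if (length(common) == 0L) {
    ex <- function(v) paste(head(v, 3L), collapse = ", ")
    sb_stop(paste0(
      "no cells shared between matrix (%d cells, e.g. %s), ",
      "metadata (%d cells, e.g. %s) and layouts (%d cells, e.g. %s)"),
      length(matrix$cell_ids), ex(matrix$cell_ids),
      length(cells$cell_ids), ex(cells$cell_ids),
      length(layouts[[1L]]$cell_ids), ex(layouts[[1L]]$cell_ids))
  }
  drop_m <- length(matrix$cell_ids) - length(common)
  drop_c <- length(cells$cell_ids) - length(common)
  if (drop_m > 0L) log <- sb_log(log, "dropped %d cells from matrix (not in all sources)", drop_m)
  if (drop_c > 0L) log <- sb_log(log, "dropped %d cells from metadata (not in all sources)", drop_c)

  mi <- match(common, matrix$cell_ids)
  m2 <- sb_matrix(matrix$gene_ids, common,
                  matrix$values[, mi, drop = FALSE],
                  aliases = matrix$aliases)
  ci <- match(common, cells$cell_ids)
  c2 <- sb_cells(common, lapply(cells$fields, function(v) {
    if (inherits(v, "sb_field")) reindex_field(v, ci) else v[ci]
  }))
  l2 <- lapply(layouts, function(ly) {
    drop_l <- length(ly$cell_ids) - length(common)
    if (drop_l > 0L)
      log <<- sb_log(log, "dropped %d cells from layout '%s' (not in all sources)",
                     drop_l, ly$name)
    li <- match(common, ly$cell_ids)
    sb_layout(ly$name, common, ly$x[li], ly$y[li], n_dropped = ly$n_dropped)
  })
  dg <- character(0)
  if (length(dataset_genes)) {
    ok <- !is.na(vapply(dataset_genes, function(g) resolve_gene(m2, g), 1L))
    if (any(!ok))
      log <- sb_log(log, "dropped %d dataset genes not present in the matrix",
                    sum(!ok))
    dg <- dataset_genes[ok]
  }
  structure(list(matrix = m2, cells = c2, layouts = l2,
                 dataset_genes = dg, log = log),
            class = "sb_dataset")
}

#' Strip a trailing barcode suffix from cell identifiers
#'
#' Cell-id matching across sources is exact by default; this opt-in helper
#' (the CLI's `--strip-suffix`) removes a trailing `-<digit>` (e.g. the
#' Cellranger `-1` lane suffix) before alignment.
#'
#' @param ids Character vector of cell ids.
#' @return Character vector with any trailing `-<digit>` removed.
#' @export
strip_barcode_suffix <- function(ids) {
  sub("-[0-9]$", "", ids)
}
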