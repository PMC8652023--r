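# AnnData (h5ad) and Loom are both plain HDF5 layouts; reading and writing
# go through rhdf5 directly. The readers accept the subsets of the two
# formats that Scanpy/Seurat exports actually produce: dense or CSR/CSC X,
# string/numeric/categorical obs columns, 2D (or wider) obsm embeddings.

h5_children <- function(path, group) {
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  ls$name[ls$group == group]
}

h5_is_group <- function(path, name) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  any(ls$name == sub("^/", "", name) & ls$otype == "H5I_GROUP")
}

# X may be dense (n_obs x n_vars) or a csr/csc group (data/indices/indptr)
read_h5ad_X <- function(path, n_obs, n_vars) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  row <- ls[ls$name == "X", , drop = FALSE]
  if (nrow(row) == 0L) sb_stop("h5ad file '%s' has no X matrix", path)
  if (row$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- tryCatch(rhdf5::h5readAttributes(path, "X")[["encoding-type"]],
                    error = function(e) NULL)
    if (is.null(enc)) enc <- if (length(indptr) == n_obs + 1L) "csr_matrix" else "csc_matrix"
    if (identical(enc, "csr_matrix")) {
      # CSR over obs x var == CSC over var x obs: exactly the gene x cell
      # orientation we want
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                x = data, dims = c(n_vars, n_obs))
    } else {
      m <- Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                          x = data, dims = c(n_obs, n_vars)))
    }
    m
  } else {
    # h5py writes obs x var row-major; rhdf5 reads it as var x obs
    x <- rhdf5::h5read(path, "X")
    if (!identical(dim(x), c(n_vars, n_obs))) x <- t(x)
    x
  }
}

h5_as_char <- function(x) {
  if (is.factor(x)) as.character(x) else as.character(as.vector(x))
}

# one obs column: plain array, or a categorical group (categories + codes)
read_h5ad_obs_col <- function(path, col) {
  node <- paste0("obs/", col)
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  row <- ls[paste0(ls$group, "/", ls$name) %in% paste0("/", node), , drop = FALSE]
  if (nrow(row) && row$otype[1L] == "H5I_GROUP") {
    cats <- h5_as_char(rhdf5::h5read(path, paste0(node, "/categories")))
    codes <- as.integer(rhdf5::h5read(path, paste0(node, "/codes")))
    out <- rep(NA_character_, length(codes))
    out[codes >= 0L] <- cats[codes[codes >= 0L] + 1L]
    ifelse(is.na(out), "", out)
  } else {
    h5_as_char(rhdf5::h5read(path, node))
  }
}

#' Read an AnnData h5ad file
#'
#' Extracts the main matrix (transposed to gene x cell), the per-cell
#' annotation columns, and every 2-or-more-column `obsm` embedding as a
#' layout (named from its key with a leading `"X_"` stripped; only the
#' first two columns of wider embeddings are used). A file without any 2D
#' embedding yields an empty layout list with a warning — the bundle build
#' will fail later if no layout is supplied another way.
#'
#' @param path h5ad file.
#' @return A list with `matrix` ([sb_matrix]), `cells` ([sb_cells]),
#'   `layouts` (list of [sb_layout]).
#' @export
read_matrix_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  obs_index <- h5_as_char(read_h5_index(path, "obs"))
  var_index <- h5_as_char(read_h5_index(path, "var"))
  m <- read_h5ad_X(path, length(obs_index), length(var_index))
  em <- sb_matrix(var_index, obs_index, m)

  cols <- setdiff(h5_children(path, "/obs"), c("_index", "index"))
  # column-order attribute, when present, fixes the field order
  ord <- tryCatch(rhdf5::h5readAttributes(path, "obs")[["column-order"]],
                  error = function(e) NULL)
  if (!is.null(ord)) cols <- intersect(as.character(ord), cols)
  fields <- lapply(cols, function(cl) read_h5ad_obs_col(path, cl))
  names(fields) <- cols
  cells <- sb_cells(obs_index, fields)

  layouts <- list()
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  if ("obsm" %in% ls$name) {
    for (key in h5_children(path, "/obsm")) {
      emb <- rhdf5::h5read(path, paste0("obsm/", key))
      # h5py writes n_obs x k row-major; rhdf5 reads k x n_obs
      if (nrow(emb) > ncol(emb) && ncol(emb) >= 2L) emb <- t(emb)
      if (nrow(emb) < 2L) next
      nm <- sub("^X_", "", key)
      layouts[[nm]] <- sb_layout(nm, obs_index, emb[1L, ], emb[2L, ])
    }
  }
  if (length(layouts) == 0L)
    sb_warn("h5ad file '%s' has no 2D embedding; layouts must come from elsewhere", path)
  list(matrix = em, cells = cells, layouts = unname(layouts))
}

read_h5_index <- function(path, group) {
  idx_name <- tryCatch(rhdf5::h5readAttributes(path, group)[["_index"]],
                       error = function(e) NULL)
  if (is.null(idx_name)) idx_name <- "_index"
  rhdf5::h5read(path, paste0(group, "/", idx_name))
}

# attach AnnData on-disk encoding attributes so Python's anndata reads the
# file natively (index names, dataframe column order, array encodings)
h5ad_attr <- function(path, obj, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  is_group <- h5_is_group_at(fid, obj)
  oid <- if (is_group) rhdf5::H5Gopen(fid, obj) else rhdf5::H5Dopen(fid, obj)
  on.exit(if (is_group) rhdf5::H5Gclose(oid) else rhdf5::H5Dclose(oid),
          add = TRUE, after = FALSE)
  for (nm in names(attrs))
    rhdf5::h5writeAttribute(attrs[[nm]], oid, nm, asScalar = length(attrs[[nm]]) == 1L)
}

h5_is_group_at <- function(fid, obj) {
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid))
  grepl("GROUP", rhdf5::H5Iget_type(oid))
}

#' Write a dataset as a minimal AnnData h5ad file
#'
#' Emits the dense-X AnnData layout (X as obs x var, obs columns as string
#' arrays, obsm embeddings as `X_<name>` arrays) that [read_matrix_h5ad()]
#' and Python's anndata both read.
#'
#' @param matrix An [sb_matrix].
#' @param cells An [sb_cells] with raw or typed fields.
#' @param layouts List of [sb_layout]s.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_h5ad <- function(matrix, cells, layouts, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  # R matrix gene x cell written column-major == obs x var row-major for h5py
  dense <- as.matrix(matrix$values)
  rhdf5::h5write(dense, path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(matrix$cell_ids, path, "obs/_index")
  for (nm in names(cells$fields)) {
    v <- cells$fields[[nm]]
    if (inherits(v, "sb_field")) v <- decode_field(v)
    rhdf5::h5write(as.character(v), path, paste0("obs/", nm))
  }
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(matrix$gene_ids, path, "var/_index")
  rhdf5::h5createGroup(path, "obsm")
  for (ly in layouts) {
    # write k x n_obs from R so h5py sees n_obs x k
    rhdf5::h5write(rbind(ly$x, ly$y), path, paste0("obsm/X_", ly$name))
  }
  rhdf5::h5closeAll()

  str_enc <- c("encoding-type" = "string-array", "encoding-version" = "0.2.0")
  arr_enc <- c("encoding-type" = "array", "encoding-version" = "0.2.0")
  h5ad_attr(path, "/", c("encoding-type" = "anndata",
                         "encoding-version" = "0.1.0"))
  h5ad_attr(path, "X", arr_enc)
  h5ad_attr(path, "obs", list("encoding-type" = "dataframe",
                              "encoding-version" = "0.2.0",
                              "_index" = "_index",
                              "column-order" = if (length(cells$fields))
                                names(cells$fields) else numeric(0)))
  h5ad_attr(path, "obs/_index", str_enc)
  for (nm in names(cells$fields)) h5ad_attr(path, paste0("obs/", nm), str_enc)
  h5ad_attr(path, "var", list("encoding-type" = "dataframe",
                              "encoding-version" = "0.2.0",
                              "_index" = "_index",
                              "column-order" = numeric(0)))
  h5ad_attr(path, "var/_index", str_enc)
  h5ad_attr(path, "obsm", c("encoding-type" = "dict",
                            "encoding-version" = "0.1.0"))
  for (ly in layouts) h5ad_attr(path, paste0("obsm/X_", ly$name), arr_enc)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a Loom file
#'
#' Loom stores the matrix gene x cell with gene ids in a row attribute and
#' cell ids in a column attribute. Paired column attributes following the
#' coordinate suffix conventions become layouts: `<stem>_X`/`<stem>_Y`
#' (empty stem gives layout name `"layout"`) and `<stem>1`/`<stem>2` (e.g.
#' `_tSNE1`/`_tSNE2` becomes layout `"tSNE"`). All other column attributes
#' become metadata fields.
#'
#' @param path Loom file.
#' @param gene_attr,cell_attr Attribute names to try, in order.
#' @return A list with `matrix`, `cells`, `layouts` as [read_matrix_h5ad()].
#' @export
read_matrix_loom <- function(path,
                             gene_attr = c("Gene", "GeneID", "gene_names", "var_names"),
                             cell_attr = c("CellID", "obs_names", "cell_names")) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  row_attrs <- h5_children(path, "/row_attrs")
  col_attrs <- h5_children(path, "/col_attrs")
  ga <- gene_attr[gene_attr %in% row_attrs][1L]
  if (is.na(ga))
    sb_stop("no gene id attribute in '%s'; row attributes present: %s",
            path, paste(row_attrs, collapse = ", "))
  ca <- cell_attr[cell_attr %in% col_attrs][1L]
  if (is.na(ca))
    sb_stop("no cell id attribute in '%s'; column attributes present: %s",
            path, paste(col_attrs, collapse = ", "))
  gene_ids <- h5_as_char(rhdf5::h5read(path, paste0("row_attrs/", ga)))
  cell_ids <- h5_as_char(rhdf5::h5read(path, paste0("col_attrs/", ca)))
  m <- rhdf5::h5read(path, "matrix")
  # loom matrix is genes x cells row-major; rhdf5 reads cells x genes
  if (!identical(dim(m), c(length(gene_ids), length(cell_ids)))) m <- t(m)
  em <- sb_matrix(gene_ids, cell_ids, m)

  layouts <- list()
  used <- character(0)
  for (a in col_attrs) {
    if (grepl("_X$", a)) {
      ymate <- sub("_X$", "_Y", a)
      if (ymate %in% col_attrs) {
        stem <- sub("_X$", "", a)
        nm <- if (stem == "") "layout" else sub("^_", "", stem)
        layouts[[nm]] <- sb_layout(nm, cell_ids,
                                   as.numeric(rhdf5::h5read(path, paste0("col_attrs/", a))),
                                   as.numeric(rhdf5::h5read(path, paste0("col_attrs/", ymate))))
        used <- c(used, a, ymate)
      }
    } else if (grepl("1$", a)) {
      mate <- sub("1$", "2", a)
      if (mate %in% col_attrs) {
        nm <- sub("^_", "", sub("1$", "", a))
        layouts[[nm]] <- sb_layout(nm, cell_ids,
                                   as.numeric(rhdf5::h5read(path, paste0("col_attrs/", a))),
                                   as.numeric(rhdf5::h5read(path, paste0("col_attrs/", mate))))
        used <- c(used, a, mate)
      }
    }
  }
  meta_cols <- setdiff(col_attrs, c(ca, used))
  # honor a recorded column order when present (our writer emits one);
  # otherwise attributes come back in HDF5 (alphabetical) order
  ord <- tryCatch(rhdf5::h5readAttributes(path, "col_attrs")[["column_order"]],
                  error = function(e) NULL)
  if (!is.null(ord)) meta_cols <- intersect(as.character(ord), meta_cols)
  fields <- lapply(meta_cols, function(a)
    h5_as_char(rhdf5::h5read(path, paste0("col_attrs/", a))))
  names(fields) <- meta_cols
  cells <- sb_cells(cell_ids, fields)
  list(matrix = em, cells = cells, layouts = unname(layouts))
}

#' Write a dataset as a Loom file
#'
#' @param matrix An [sb_matrix].
#' @param cells An [sb_cells].
#' @param layouts List of [sb_layout]s; each becomes a `<name>1`/`<name>2`
#'   column attribute pair.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_loom <- function(matrix, cells, layouts, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  # write cells x genes from R so HDF5 holds genes x cells row-major
  rhdf5::h5write(t(as.matrix(matrix$values)), path, "matrix")
  rhdf5::h5createGroup(path, "row_attrs")
  rhdf5::h5write(matrix$gene_ids, path, "row_attrs/Gene")
  rhdf5::h5createGroup(path, "col_attrs")
  rhdf5::h5write(matrix$cell_ids, path, "col_attrs/CellID")
  for (nm in names(cells$fields)) {
    v <- cells$fields[[nm]]
    if (inherits(v, "sb_field")) v <- decode_field(v)
    rhdf5::h5write(as.character(v), path, paste0("col_attrs/", nm))
  }
  for (ly in layouts) {
    rhdf5::h5write(ly$x, path, paste0("col_attrs/", ly$name, "1"))
    rhdf5::h5write(ly$y, path, paste0("col_attrs/", ly$name, "2"))
  }
  rhdf5::h5closeAll()
  if (length(cells$fields))
    h5ad_attr(path, "col_attrs",
              list(column_order = names(cells$fields)))
  rhdf5::h5closeAll()
  invisible(path)
}
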