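BUNDLE_FORMAT_VERSION <- 1L

# config keys the parser understands; anything else warns
KNOWN_CONFIG_KEYS <- c(
  "name", "shortLabel", "matrix", "matrixFormat", "features", "barcodes",
  "genesIn", "meta", "coords", "clusterField", "datasetGenes", "bins",
  "palette", "exprPalette", "stripSuffix", "atacPeaks", "atacGenes",
  "atacWindow", "images")

parse_config_value <- function(raw) {
  raw <- trimws(raw)
  if (grepl("^\\[", raw)) {
    inner <- sub("^\\[", "", sub("\\]$", "", raw))
    if (trimws(inner) == "") return(character(0))
    items <- regmatches(inner, gregexpr('"[^"]*"', inner))[[1L]]
    return(gsub('^"|"$', "", items))
  }
  if (grepl('^".*"$', raw)) return(gsub('^"|"$', "", raw))
  if (raw %in% c("true", "false")) return(raw == "true")
  num <- suppressWarnings(as.numeric(raw))
  if (!is.na(num)) return(num)
  raw
}

#' Parse a dataset build configuration
#'
#' The config is a flat `key=value` text file (quoted strings, bracketed
#' lists, `#` comment lines). Paths are resolved relative to the config
#' file. Required keys: `name` and `matrix` always; `meta` and at least one
#' `coords` entry unless the matrix format (h5ad, loom) embeds them.
#' Unknown keys produce a warning, not an error. Defaults are filled in:
#' `bins=10`, `palette="classic12"`, `exprPalette="whiteRed"`,
#' `atacWindow=100000`.
#'
#' `coords` entries are `"path:label"` strings; `matrixFormat` is inferred
#' from the matrix file extension when absent (`mtx`, `h5ad`, `loom`, else
#' `dense`). `images` is an opaque passthrough list copied verbatim into
#' the manifest.
#'
#' @param path Config file.
#' @return An `sb_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) sb_stop("config file '%s' not found", path)
  lines <- readLines(path)
  cfg <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) sb_stop("config line %d is not key=value: '%s'", i, ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    if (!key %in% KNOWN_CONFIG_KEYS)
      sb_warn("unknown config key '%s' (line %d) ignored", key, i)
    cfg[[key]] <- parse_config_value(substr(ln, eq + 1L, nchar(ln)))
  }
  base <- dirname(normalizePath(path))
  respath <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }

  for (k in c("name", "matrix")) {
    if (is.null(cfg[[k]])) sb_stop("config is missing required key '%s'", k)
  }
  if (!grepl("^[A-Za-z0-9_-]+$", cfg$name))
    sb_stop("dataset name '%s' must match [A-Za-z0-9_-]+", cfg$name)
  if (is.null(cfg$matrixFormat)) {
    cfg$matrixFormat <- if (grepl("\\.mtx(\\.gz)?$", cfg$matrix)) "mtx"
      else if (grepl("\\.h5ad$", cfg$matrix)) "h5ad"
      else if (grepl("\\.loom$", cfg$matrix)) "loom"
      else "dense"
  }
  embedded <- cfg$matrixFormat %in% c("h5ad", "loom")
  if (!embedded) {
    if (is.null(cfg$meta)) sb_stop("config is missing required key 'meta'")
    if (is.null(cfg$coords) || length(cfg$coords) == 0L)
      sb_stop("config is missing required key 'coords' (need at least one layout)")
  }
  if (cfg$matrixFormat == "mtx") {
    for (k in c("features", "barcodes"))
      if (is.null(cfg[[k]]))
        sb_stop("config is missing required key '%s' (needed for mtx)", k)
  }
  defaults <- list(shortLabel = cfg$name, bins = 10, palette = "classic12",
                   exprPalette = "whiteRed", atacWindow = 1e5,
                   stripSuffix = FALSE, genesIn = "rows",
                   clusterField = NULL, datasetGenes = NULL,
                   images = list())
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]

  coords <- list()
  if (!is.null(cfg$coords)) {
    for (entry in cfg$coords) {
      parts <- strsplit(entry, ":", fixed = TRUE)[[1L]]
      if (length(parts) == 1L) parts <- c(parts, tools::file_path_sans_ext(basename(parts)))
      coords[[length(coords) + 1L]] <- list(path = respath(parts[1L]),
                                            label = parts[2L])
    }
  }
  cfg$coords <- coords
  for (k in c("matrix", "features", "barcodes", "meta", "datasetGenes",
              "atacPeaks", "atacGenes"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- respath(cfg[[k]])
  missing_paths <- character(0)
  for (k in c("matrix", "features", "barcodes", "meta", "datasetGenes",
              "atacPeaks", "atacGenes"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      missing_paths <- c(missing_paths, sprintf("%s (%s)", k, cfg[[k]]))
  for (co in cfg$coords)
    if (!file.exists(co$path))
      missing_paths <- c(missing_paths, sprintf("coords (%s)", co$path))
  if (length(missing_paths))
    sb_stop("config references missing files: %s",
            paste(missing_paths, collapse = "; "))
  structure(cfg, class = "sb_config")
}

# import stage: dispatch on matrixFormat, returning matrix/cells/layouts
import_dataset_inputs <- function(cfg) {
  fmt <- cfg$matrixFormat
  if (fmt == "mtx") {
    em <- read_matrix_mtx(cfg$matrix, cfg$features, cfg$barcodes)
    cells <- NULL; layouts <- list()
  } else if (fmt == "dense") {
    em <- read_matrix_dense(cfg$matrix, genes_in = cfg$genesIn)
    cells <- NULL; layouts <- list()
  } else if (fmt == "h5ad") {
    r <- read_matrix_h5ad(cfg$matrix)
    em <- r$matrix; cells <- r$cells; layouts <- r$layouts
  } else if (fmt == "loom") {
    r <- read_matrix_loom(cfg$matrix)
    em <- r$matrix; cells <- r$cells; layouts <- r$layouts
  } else {
    sb_stop("unknown matrix format '%s'", fmt)
  }
  # explicit meta/coords files override container-embedded ones
  if (!is.null(cfg$meta)) cells <- read_annotations(cfg$meta)
  if (is.null(cells)) sb_stop("no metadata: config has no 'meta' and the matrix embeds none")
  if (length(cfg$coords)) {
    layouts <- lapply(cfg$coords, function(co) read_layout(co$path, co$label))
  }
  if (length(layouts) == 0L)
    sb_stop("no layouts: config has no 'coords' and the matrix embeds none")
  if (isTRUE(cfg$stripSuffix)) {
    em$cell_ids <- strip_barcode_suffix(em$cell_ids)
    cells$cell_ids <- strip_barcode_suffix(cells$cell_ids)
    layouts <- lapply(layouts, function(ly) {
      ly$cell_ids <- strip_barcode_suffix(ly$cell_ids); ly
    })
  }
  list(matrix = em, cells = cells, layouts = layouts)
}

#' Build a static dataset bundle
#'
#' Runs the full pipeline — import, cell alignment, per-gene store build,
#' field typing and coloring, heatmap table — and writes a self-contained
#' bundle directory: `dataset.json` (manifest), `exprMatrix.bin` +
#' `exprMatrix.json` (per-gene store), `meta.tsv.gz`,
#' `coords/<label>.tsv.gz`, `heatmap.tsv` and, in ATAC mode, copies of the
#' peak/gene-model files. Every downstream query runs against this
#' directory alone; a static file server is all that is needed to host it.
#' Re-running on unchanged inputs produces byte-identical output (no
#' timestamps are written).
#'
#' @param config An `sb_config` from [parse_config()] (or a path to one).
#' @param out_dir Bundle output directory (created; must be empty or new).
#' @return An `sb_bundle` handle from [load_bundle()].
#' @export
build_dataset <- function(config, out_dir) {
  if (is.character(config)) config <- parse_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      sb_stop("build stage '%s' failed: %s", name, conditionMessage(e)))
  }
  inputs <- stage("import", import_dataset_inputs(config))
  dataset_genes <- character(0)
  if (!is.null(config$datasetGenes)) {
    dataset_genes <- trimws(readLines(config$datasetGenes))
    dataset_genes <- dataset_genes[dataset_genes != ""]
  }
  ds <- stage("align", align_cells(inputs$matrix, inputs$cells, inputs$layouts,
                                   dataset_genes))
  log <- ds$log
  for (ly in inputs$layouts)
    if (ly$n_dropped > 0L)
      log <- sb_log(log, "layout '%s': dropped %d rows with non-finite coordinates",
                    ly$name, ly$n_dropped)

  # type every metadata field; categorical fields get palette colors
  fields <- stage("annotate", {
    out <- list()
    for (nm in names(ds$cells$fields)) {
      f <- infer_field_kind(nm, ds$cells$fields[[nm]])
      if (f$kind == "categorical") f <- assign_colors(f, config$palette)
      out[[nm]] <- f
    }
    out
  })
  if (!is.null(config$clusterField)) {
    cf <- fields[[config$clusterField]]
    if (is.null(cf))
      sb_stop("build stage 'annotate' failed: cluster field '%s' not in metadata (fields: %s)",
              config$clusterField, paste(names(fields), collapse = ", "))
    if (cf$kind != "categorical")
      sb_stop("build stage 'annotate' failed: cluster field '%s' is %s, not categorical",
              config$clusterField, cf$kind)
  }

  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    sb_stop("cannot create bundle directory '%s'", out_dir)
  store <- stage("store", build_store(ds$matrix, out_dir))

  # metadata with decoded values; first column is the cell identifier
  meta_dt <- data.table::data.table(cellId = ds$cells$cell_ids)
  for (nm in names(fields)) {
    v <- decode_field(fields[[nm]])
    meta_dt[[nm]] <- if (is.numeric(v)) ifelse(is.na(v), "NA", as.character(v)) else v
  }
  write_tsv_gz(meta_dt, file.path(out_dir, "meta.tsv.gz"))

  dir.create(file.path(out_dir, "coords"), showWarnings = FALSE)
  layout_entries <- list()
  for (ly in ds$layouts) {
    fn <- paste0(gsub("[^A-Za-z0-9_-]", "_", ly$name), ".tsv.gz")
    write_tsv_gz(data.table::data.table(cellId = ly$cell_ids,
                                        x = as.character(ly$x),
                                        y = as.character(ly$y)),
                 file.path(out_dir, "coords", fn))
    layout_entries[[length(layout_entries) + 1L]] <-
      list(name = ly$name, file = file.path("coords", fn))
  }

  heatmap_file <- NULL
  if (!is.null(config$clusterField) && length(ds$dataset_genes)) {
    hm <- stage("heatmap",
      cluster_means(store, fields[[config$clusterField]], ds$cells$cell_ids,
                    ds$dataset_genes))
    write_heatmap_tsv(hm, file.path(out_dir, "heatmap.tsv"))
    heatmap_file <- "heatmap.tsv"
  }

  atac <- NULL
  if (!is.null(config$atacPeaks)) {
    atac <- stage("atac", {
      file.copy(config$atacPeaks, file.path(out_dir, "peaks.bed"), overwrite = TRUE)
      a <- list(peaks_file = "peaks.bed", window = config$atacWindow)
      # fail early if the files are malformed
      load_peaks(file.path(out_dir, "peaks.bed"))
      if (!is.null(config$atacGenes)) {
        file.copy(config$atacGenes, file.path(out_dir, "geneModels.tsv"),
                  overwrite = TRUE)
        load_gene_models(file.path(out_dir, "geneModels.tsv"))
        a$genes_file <- "geneModels.tsv"
      }
      a
    })
  }

  field_entries <- lapply(names(fields), function(nm) {
    f <- fields[[nm]]
    e <- list(name = nm, kind = f$kind, n_missing = f$n_missing)
    if (f$kind == "categorical") {
      e$values <- names(f$value_dict)
      e$counts <- unname(as.integer(f$counts))
      e$colors <- unname(f$color_map)
    }
    e
  })

  manifest <- list(
    format = "scbundle-dataset",
    version = BUNDLE_FORMAT_VERSION,
    name = config$name,
    short_label = config$shortLabel,
    n_cells = length(ds$cells$cell_ids),
    n_genes = length(ds$matrix$gene_ids),
    cell_order_digest = cell_order_digest(ds$cells$cell_ids),
    bins = as.integer(config$bins),
    palettes = list(categorical = config$palette,
                    expression = config$exprPalette),
    quartile_method = "linear-interpolation",
    cluster_field = config$clusterField,
    dataset_genes = as.list(ds$dataset_genes),
    meta_file = "meta.tsv.gz",
    layouts = layout_entries,
    heatmap_file = heatmap_file,
    fields = field_entries,
    atac = atac,
    images = config$images,
    build_log = as.list(log)
  )
  write_json_file(manifest, file.path(out_dir, "dataset.json"))
  load_bundle(out_dir)
}

#' Open a built dataset bundle
#'
#' Reconstructs the typed metadata table, layouts and store handle from the
#' bundle directory alone; no original input files are touched. The
#' store's cell-order digest is checked against the manifest.
#'
#' @param dir Bundle directory.
#' @return An `sb_bundle` with `dir`, `manifest`, `store`, `cells`
#'   (typed [sb_cells]), `layouts`, `dataset_genes`, `cluster_field`.
#' @export
load_bundle <- function(dir) {
  mpath <- file.path(dir, "dataset.json")
  if (!file.exists(mpath)) sb_stop("no dataset.json in '%s'", dir)
  manifest <- read_json_file(mpath)
  if (!identical(manifest$format, "scbundle-dataset"))
    sb_stop("'%s' is not a dataset bundle manifest", mpath)
  store <- open_store(dir, expect_digest = manifest$cell_order_digest)

  meta <- sb_fread(file.path(dir, manifest$meta_file), sep = "\t",
                            header = TRUE, colClasses = "character",
                            na.strings = NULL)
  cell_ids <- meta[[1L]]
  fields <- list()
  for (fe in manifest$fields) {
    raw <- meta[[fe$name]]
    f <- infer_field_kind(fe$name, raw)
    if (f$kind == "categorical") {
      # restore the persisted dictionary order and colors verbatim
      lev <- unlist(fe$values)
      f$value_dict <- setNames(seq_along(lev) - 1L, lev)
      f$values <- unname(f$value_dict[ifelse(is_missing_marker(raw), "(missing)", raw)])
      f$counts <- setNames(as.integer(unlist(fe$counts)), lev)
      f$color_map <- setNames(unlist(fe$colors), lev)
    }
    fields[[fe$name]] <- f
  }
  cells <- sb_cells(cell_ids, fields)

  layouts <- lapply(manifest$layouts, function(le) {
    dt <- sb_fread(file.path(dir, le$file), sep = "\t", header = TRUE)
    sb_layout(le$name, as.character(dt[[1L]]), dt[[2L]], dt[[3L]])
  })
  structure(list(dir = dir, manifest = manifest, store = store,
                 cells = cells, layouts = layouts,
                 dataset_genes = unlist(manifest$dataset_genes),
                 cluster_field = manifest$cluster_field),
            class = "sb_bundle")
}

#' @export
print.sb_bundle <- function(x, ...) {
  cat(sprintf("<sb_bundle> '%s': %d cells, %d genes, %d layout(s) at %s\n",
              x$manifest$name, x$manifest$n_cells, x$manifest$n_genes,
              length(x$layouts), x$dir))
  invisible(x)
}

#' Validate a bundle directory
#'
#' Structural checks on a built bundle: the manifest parses; the store
#' index offsets are strictly increasing, non-overlapping and sum to the
#' data file size; sampled genes (first, last, and up to 20 evenly spaced)
#' decode to `n_cells` values with matching checksums; categorical field
#' counts sum to `n_cells`; every layout covers the canonical cells; the
#' store digest matches the manifest. Failures are findings in the report,
#' not errors.
#'
#' @param dir Bundle directory.
#' @return A list with `pass` (logical) and `findings` (character).
#' @export
validate_bundle <- function(dir) {
  findings <- character(0)
  note <- function(fmt, ...) findings <<- c(findings, sprintf(fmt, ...))
  if (!dir.exists(dir)) return(list(pass = FALSE, findings = "bundle directory does not exist"))
  manifest <- tryCatch(read_json_file(file.path(dir, "dataset.json")),
                       error = function(e) NULL)
  if (is.null(manifest) || !identical(manifest$format, "scbundle-dataset"))
    return(list(pass = FALSE, findings = "manifest dataset.json missing or unparseable"))
  n_cells <- manifest$n_cells

  store <- tryCatch(open_store(dir), error = function(e) {
    note("store: %s", conditionMessage(e)); NULL
  })
  if (!is.null(store)) {
    if (!identical(store$encoding$cell_order_digest, manifest$cell_order_digest))
      note("store: cell-order digest does not match manifest")
    idx <- store$index
    sizes <- file.size(store$data_path)
    if (length(idx)) {
      off <- vapply(idx, function(e) as.numeric(e[[1L]]), 1)
      len <- vapply(idx, function(e) as.numeric(e[[2L]]), 1)
      if (any(diff(off) <= 0)) note("store: index offsets not strictly increasing")
      if (any(off[-1L] != (off + len)[-length(off)]))
        note("store: index blocks overlap or leave gaps")
      if (off[length(off)] + len[length(len)] != sizes)
        note("store: index spans %g bytes but data file has %g",
             off[length(off)] + len[length(len)], sizes)
      genes <- names(idx)
      probe <- unique(c(1L, length(genes),
                        as.integer(seq(1L, length(genes), length.out = min(20L, length(genes))))))
      for (i in probe) {
        v <- tryCatch(fetch_gene(store, genes[i]), error = function(e) {
          note("store: gene '%s': %s", genes[i], conditionMessage(e)); NULL
        })
        if (!is.null(v) && length(v) != n_cells)
          note("store: gene '%s' decoded to %d values, expected %d",
               genes[i], length(v), n_cells)
      }
    } else if (sizes != 0) {
      note("store: empty index but nonempty data file")
    }
  }

  for (fe in manifest$fields) {
    if (identical(fe$kind, "categorical")) {
      s <- sum(unlist(fe$counts)) + 0
      if (s != n_cells)
        note("field '%s': counts sum to %g, expected %d", fe$name, s, n_cells)
    }
  }

  meta_ids <- tryCatch({
    dt <- sb_fread(file.path(dir, manifest$meta_file), sep = "\t",
                            header = TRUE, colClasses = "character")
    dt[[1L]]
  }, error = function(e) { note("meta: %s", conditionMessage(e)); NULL })
  if (!is.null(meta_ids)) {
    if (length(meta_ids) != n_cells)
      note("meta: %d rows, expected %d cells", length(meta_ids), n_cells)
    if (!identical(cell_order_digest(meta_ids), manifest$cell_order_digest))
      note("meta: cell order digest mismatch")
    for (le in manifest$layouts) {
      co <- tryCatch(sb_fread(file.path(dir, le$file), sep = "\t",
                                       header = TRUE, colClasses = "character"),
                     error = function(e) { note("layout '%s': %s", le$name,
                                                conditionMessage(e)); NULL })
      if (!is.null(co) && !identical(co[[1L]], meta_ids))
        note("layout '%s' does not cover the canonical cells", le$name)
    }
  }
  list(pass = length(findings) == 0L, findings = findings)
}
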