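#' Specification for a synthetic single-cell dataset
#'
#' Defines a seeded generative model with known ground truth, shaped like
#' the data the browser visualizes: a zero-inflated negative-binomial
#' count matrix with cluster-specific marker genes, per-cluster 2D
#' Gaussian blob layouts, and typical metadata (a cluster label, a numeric
#' age, a uniqueId well).
#'
#' Defaults emulate common scRNA-seq sparsity: baseline negative binomial
#' with mean 1.5 and size (dispersion) 0.25 plus dropout 0.4 gives roughly
#' 80 percent zeros, so the zero-bin discretization path is always
#' exercised; markers are upregulated 8-fold in their own cluster.
#'
#' @param n_cells,n_genes,n_clusters Dataset dimensions.
#' @param markers_per_cluster Genes upregulated per cluster; the true
#'   markers become the dataset-genes list.
#' @param nb_mean,nb_size Baseline negative-binomial mean and size.
#' @param dropout Extra zero-inflation probability per entry.
#' @param fold_change Marker mean multiplier in its own cluster.
#' @param blob_sd Within-cluster standard deviation of layout blobs
#'   (centers sit on a radius-10 circle).
#' @param n_peaks,n_atac_genes,n_chroms,chrom_len ATAC fixture shape.
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return An `sb_synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 1000L, n_genes = 200L, n_clusters = 5L,
                           markers_per_cluster = 4L, nb_mean = 1.5,
                           nb_size = 0.25, dropout = 0.4, fold_change = 8,
                           blob_sd = 1, n_peaks = 500L, n_atac_genes = 20L,
                           n_chroms = 5L, chrom_len = 1e7, seed = 1L) {
  if (n_clusters < 1L) sb_stop("need at least one cluster")
  if (markers_per_cluster * n_clusters > n_genes)
    sb_stop("markers_per_cluster * n_clusters (%d) exceeds n_genes (%d)",
            markers_per_cluster * n_clusters, n_genes)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 nb_mean = nb_mean, nb_size = nb_size, dropout = dropout,
                 fold_change = fold_change, blob_sd = blob_sd,
                 n_peaks = as.integer(n_peaks),
                 n_atac_genes = as.integer(n_atac_genes),
                 n_chroms = as.integer(n_chroms), chrom_len = chrom_len,
                 seed = as.integer(seed)),
            class = "sb_synthetic_spec")
}

# blob centers on a circle; rotation differs per layout so the two
# embeddings are distinct but share the cluster structure
blob_centers <- function(k, rotation = 0) {
  ang <- 2 * pi * (seq_len(k) - 1L) / k + rotation
  cbind(x = 10 * cos(ang), y = 10 * sin(ang))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes every input format the importers consume — MTX triple (with a
#' two-column features file exercising the accession-alias path), dense
#' TSV, metadata TSV, two layout TSVs, the dataset-genes list (the true
#' markers), an h5ad and a Loom container, a BED peak file plus gene-model
#' TSV for ATAC queries, a ready-to-build config, and a `spec.json` record
#' of every distribution parameter so the fixture is self-documenting.
#'
#' @param spec An [synthetic_spec()].
#' @param out_dir Output directory (created).
#' @return Ground truth, invisibly: `cluster` (named cell to label),
#'   `markers` (cluster to marker symbols), `centers` (per layout),
#'   `matrix` (the dense gene x cell counts), `gene_symbols`,
#'   `gene_accessions`, `cell_ids`, `peaks`, `gene_models`, `spec`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "sb_synthetic_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    sb_stop("cannot create '%s'", out_dir)
  set.seed(spec$seed)
  n <- spec$n_cells; g <- spec$n_genes; k <- spec$n_clusters

  cell_ids <- sprintf("c%05d", seq_len(n))
  symbols <- sprintf("G%03d", seq_len(g))
  accessions <- sprintf("ACC%05d", seq_len(g))
  cluster_labels <- sprintf("cluster_%d", seq_len(k))
  cluster <- sample(rep_len(seq_len(k), n))

  # markers: the first markers_per_cluster * k genes, blocked by cluster
  markers <- if (spec$markers_per_cluster > 0L) {
    split(symbols[seq_len(spec$markers_per_cluster * k)],
          rep(seq_len(k), each = spec$markers_per_cluster))
  } else {
    rep(list(character(0)), k)
  }
  names(markers) <- cluster_labels
  marker_of <- rep(NA_integer_, g)
  marker_of[seq_len(spec$markers_per_cluster * k)] <-
    rep(seq_len(k), each = spec$markers_per_cluster)

  # per-gene baseline mean jitter keeps genes distinguishable
  base_mean <- spec$nb_mean * exp(rnorm(g, 0, 0.3))
  counts <- matrix(0, nrow = g, ncol = n,
                   dimnames = list(symbols, cell_ids))
  for (i in seq_len(g)) {
    mu <- rep(base_mean[i], n)
    if (!is.na(marker_of[i]))
      mu[cluster == marker_of[i]] <- mu[cluster == marker_of[i]] * spec$fold_change
    x <- rnbinom(n, mu = mu, size = spec$nb_size)
    x[runif(n) < spec$dropout] <- 0
    counts[i, ] <- x
  }

  centers <- list(tSNE = blob_centers(k, rotation = 0),
                  UMAP = blob_centers(k, rotation = pi / k))
  layouts <- lapply(names(centers), function(nm) {
    ctr <- centers[[nm]]
    sb_layout(nm, cell_ids,
              round(ctr[cluster, "x"] + rnorm(n, 0, spec$blob_sd), 4L),
              round(ctr[cluster, "y"] + rnorm(n, 0, spec$blob_sd), 4L))
  })

  age <- round(runif(n, 20, 70))
  well <- sprintf("W%05d", sample(seq_len(n)))
  meta <- data.table::data.table(cellId = cell_ids,
                                 cluster = cluster_labels[cluster],
                                 age = as.character(age),
                                 well = well)

  # --- ATAC fixture: seeded peaks and gene models
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  p_chrom <- sample(chroms, spec$n_peaks, replace = TRUE)
  p_start <- floor(runif(spec$n_peaks, 0, spec$chrom_len - 1000))
  p_width <- floor(runif(spec$n_peaks, 200, 1000))
  ag_chrom <- sample(chroms, spec$n_atac_genes, replace = TRUE)
  ag_start <- floor(runif(spec$n_atac_genes, 0, spec$chrom_len - 2e5))
  ag_len <- floor(runif(spec$n_atac_genes, 5e3, 1e5))
  gene_models <- data.frame(
    symbol = sprintf("AG%03d", seq_len(spec$n_atac_genes)),
    chrom = ag_chrom, strand = sample(c("+", "-"), spec$n_atac_genes, TRUE),
    txStart = ag_start, txEnd = ag_start + ag_len, stringsAsFactors = FALSE)

  # --- write everything
  w <- function(...) file.path(out_dir, ...)
  dir.create(w("mtx"), showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  w("mtx", "matrix.mtx"))
  writeLines(paste(accessions, symbols, sep = "\t"), w("mtx", "features.tsv"))
  writeLines(cell_ids, w("mtx", "barcodes.tsv"))

  dense <- data.table::data.table(gene = symbols)
  for (j in seq_len(n)) dense[[cell_ids[j]]] <- as.character(counts[, j])
  con <- file(w("exprMatrix.tsv"), "wb")
  writeLines(c(paste(names(dense), collapse = "\t"),
               do.call(paste, c(dense, sep = "\t"))), con, sep = "\n")
  close(con)

  data.table::fwrite(meta, w("meta.tsv"), sep = "\t", quote = FALSE)
  for (ly in layouts) {
    data.table::fwrite(data.table::data.table(cellId = ly$cell_ids,
                                              x = as.character(ly$x),
                                              y = as.character(ly$y)),
                       w(paste0(tolower(ly$name), ".coords.tsv")),
                       sep = "\t", quote = FALSE)
  }
  writeLines(unlist(markers, use.names = FALSE), w("datasetGenes.txt"))

  bed <- data.frame(p_chrom, format(p_start, scientific = FALSE, trim = TRUE),
                    format(p_start + p_width, scientific = FALSE, trim = TRUE))
  data.table::fwrite(bed, w("peaks.bed"), sep = "\t", quote = FALSE,
                     col.names = FALSE)
  gm_out <- gene_models
  gm_out$txStart <- format(gm_out$txStart, scientific = FALSE, trim = TRUE)
  gm_out$txEnd <- format(gm_out$txEnd, scientific = FALSE, trim = TRUE)
  data.table::fwrite(gm_out, w("geneModels.tsv"), sep = "\t", quote = FALSE)

  em <- sb_matrix(symbols, cell_ids, counts,
                  aliases = setNames(symbols, accessions))
  cells <- sb_cells(cell_ids, as.list(meta)[-1L])
  write_h5ad(em, cells, layouts, w("data.h5ad"))
  write_loom(em, cells, layouts, w("data.loom"))

  writeLines(c(
    'name="synthetic"',
    'shortLabel="Synthetic clustered dataset"',
    'matrix="mtx/matrix.mtx"',
    'matrixFormat="mtx"',
    'features="mtx/features.tsv"',
    'barcodes="mtx/barcodes.tsv"',
    'meta="meta.tsv"',
    'coords=["tsne.coords.tsv:tSNE", "umap.coords.tsv:UMAP"]',
    'clusterField="cluster"',
    'datasetGenes="datasetGenes.txt"',
    'atacPeaks="peaks.bed"',
    'atacGenes="geneModels.tsv"',
    'atacWindow=100000'
  ), w("dataset.conf"))

  write_json_file(unclass(spec), w("spec.json"))

  truth <- list(cluster = setNames(cluster_labels[cluster], cell_ids),
                markers = markers,
                centers = centers,
                matrix = counts,
                gene_symbols = symbols,
                gene_accessions = accessions,
                cell_ids = cell_ids,
                age = setNames(age, cell_ids),
                well = setNames(well, cell_ids),
                peaks = data.frame(chrom = p_chrom, start = p_start,
                                   end = p_start + p_width,
                                   stringsAsFactors = FALSE),
                gene_models = gene_models,
                spec = spec)
  invisible(truth)
}
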