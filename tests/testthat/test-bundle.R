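# config parsing, bundle builds, validation, static self-sufficiency

minimal_inputs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("g\tc1\tc2", "gA\t1\t0", "gB\t2\t3"),
             file.path(dir, "expr.tsv"))
  writeLines(c("cell\tgrp", "c1\ta", "c2\tb"), file.path(dir, "meta.tsv"))
  writeLines(c("cell\tx\ty", "c1\t0\t0", "c2\t1\t1"),
             file.path(dir, "coords.tsv"))
  dir
}

test_that("a minimal config parses with defaults filled in", {
  d <- minimal_inputs(tempfile())
  conf <- file.path(d, "ds.conf")
  writeLines(c('name="mini"', 'matrix="expr.tsv"', 'meta="meta.tsv"',
               'coords=["coords.tsv:main"]'), conf)
  cfg <- parse_config(conf)
  expect_equal(cfg$name, "mini")
  expect_equal(cfg$bins, 10)
  expect_equal(cfg$palette, "classic12")
  expect_equal(cfg$exprPalette, "whiteRed")
  expect_equal(cfg$atacWindow, 1e5)
  expect_equal(cfg$matrixFormat, "dense")
  expect_equal(cfg$coords[[1]]$label, "main")
})

test_that("missing required config keys fail naming the key; unknown keys warn", {
  d <- minimal_inputs(tempfile())
  conf <- file.path(d, "bad.conf")
  writeLines(c('name="mini"', 'matrix="expr.tsv"',
               'coords=["coords.tsv:main"]'), conf)
  expect_error(parse_config(conf), "'meta'")
  conf2 <- file.path(d, "warn.conf")
  writeLines(c('name="mini"', 'matrix="expr.tsv"', 'meta="meta.tsv"',
               'coords=["coords.tsv:main"]', 'shoeSize=42'), conf2)
  expect_warning(parse_config(conf2), "shoeSize")
})

test_that("the generator's emitted config parses to the generator's own values", {
  s <- syn_small()
  cfg <- parse_config(file.path(s$dir, "dataset.conf"))
  expect_equal(cfg$name, "synthetic")
  expect_equal(cfg$clusterField, "cluster")
  expect_equal(cfg$matrixFormat, "mtx")
  expect_equal(vapply(cfg$coords, `[[`, "", "label"), c("tSNE", "UMAP"))
  expect_equal(cfg$atacWindow, 1e5)
})

test_that("a minimal dataset builds into a bundle that validates", {
  d <- minimal_inputs(tempfile())
  conf <- file.path(d, "ds.conf")
  writeLines(c('name="mini"', 'matrix="expr.tsv"', 'meta="meta.tsv"',
               'coords=["coords.tsv:main"]'), conf)
  b <- build_dataset(conf, file.path(d, "out"))
  rep <- validate_bundle(file.path(d, "out"))
  expect_true(rep$pass)
  expect_equal(b$manifest$n_cells, 2)
  expect_equal(fetch_gene(b$store, "gB"), c(2, 3))
})

test_that("a cluster field absent from the metadata aborts the build by name", {
  d <- minimal_inputs(tempfile())
  conf <- file.path(d, "ds.conf")
  writeLines(c('name="mini"', 'matrix="expr.tsv"', 'meta="meta.tsv"',
               'coords=["coords.tsv:main"]', 'clusterField="nothere"'), conf)
  expect_error(build_dataset(conf, file.path(d, "out")), "nothere")
})

test_that("rebuilding from unchanged inputs is byte-identical", {
  s <- syn_small()
  o1 <- tempfile(); o2 <- tempfile()
  build_dataset(file.path(s$dir, "dataset.conf"), o1)
  build_dataset(file.path(s$dir, "dataset.conf"), o2)
  files <- list.files(o1, recursive = TRUE)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(
      readBin(file.path(o1, f), "raw", file.size(file.path(o1, f))),
      readBin(file.path(o2, f), "raw", file.size(file.path(o2, f))),
      label = f)
  }
})

test_that("every query runs from the bundle directory after inputs are deleted", {
  src <- tempfile()
  truth <- generate_dataset(
    synthetic_spec(n_cells = 150, n_genes = 40, n_clusters = 3, seed = 9), src)
  out <- tempfile()
  build_dataset(file.path(src, "dataset.conf"), out)
  unlink(src, recursive = TRUE)

  b <- load_bundle(out)
  g <- "G003"
  expect_equal(fetch_gene(b$store, g), unname(truth$matrix[g, ]))
  sel <- select_cells(b$cells, sb_query(pred("cluster", "equals", "cluster_2")))
  expect_setequal(sel, names(truth$cluster)[truth$cluster == "cluster_2"])
  vs <- violin_stats(b$store, g, sel, b$cells$cell_ids)
  in_cl <- truth$cluster == "cluster_2"
  expect_equal(vs$group_a$mean, mean(truth$matrix[g, in_cl]))
  expect_equal(vs$group_b$mean, mean(truth$matrix[g, !in_cl]))
  hm <- cluster_means(b$store, b$cells$fields$cluster, b$cells$cell_ids,
                      b$dataset_genes)
  expect_equal(hm$matrix["cluster_1", "G001"],
               mean(truth$matrix["G001", truth$cluster == "cluster_1"]),
               tolerance = 1e-6)
  # ATAC files traveled into the bundle
  peaks <- load_peaks(file.path(out, b$manifest$atac$peaks_file))
  expect_gt(length(peaks$start), 0)
})

test_that("validation flags a truncated store data file", {
  s <- syn_small()
  out <- tempfile()
  build_dataset(file.path(s$dir, "dataset.conf"), out)
  bin <- file.path(out, "exprMatrix.bin")
  raw <- readBin(bin, "raw", file.size(bin))
  writeBin(raw[seq_len(length(raw) - 1L)], bin)
  rep <- validate_bundle(out)
  expect_false(rep$pass)
  expect_match(rep$findings, "store", all = FALSE)
})

test_that("random single-byte corruptions either decode identically or are reported", {
  s <- syn_small()
  out <- tempfile()
  build_dataset(file.path(s$dir, "dataset.conf"), out)
  bin <- file.path(out, "exprMatrix.bin")
  pristine <- readBin(bin, "raw", file.size(bin))
  baseline <- lapply(list_genes(load_bundle(out)$store), function(g)
    fetch_gene(load_bundle(out)$store, g))
  set.seed(4)
  for (i in 1:25) {
    mutated <- pristine
    pos <- sample(length(mutated), 1)
    mutated[pos] <- xor(mutated[pos], as.raw(sample(1:255, 1)))
    writeBin(mutated, bin)
    st <- open_store(out)
    decoded <- tryCatch(
      lapply(list_genes(st), function(g) fetch_gene(st, g)),
      error = function(e) e)
    if (inherits(decoded, "error")) {
      expect_match(conditionMessage(decoded), "corruption")
    } else {
      expect_identical(decoded, baseline)
    }
  }
  writeBin(pristine, bin)
})
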