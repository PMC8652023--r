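# headless renderers; assertions run against render reports, never pixels

test_that("scatter legends conserve cell counts for categorical coloring", {
  b <- syn_small_bundle()
  out <- tempfile(fileext = ".svg")
  rep <- render_scatter(b, "tSNE", "cluster", out)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".report.json")))
  expect_equal(rep$n_points, b$manifest$n_cells)
  counts <- vapply(rep$legend, `[[`, 1L, "count")
  expect_equal(sum(counts), b$manifest$n_cells)
  expect_equal(vapply(rep$legend, `[[`, "", "label"),
               names(b$cells$fields$cluster$value_dict))
})

test_that("per-color point counts match the true cluster sizes", {
  s <- syn_small(); b <- syn_small_bundle()
  rep <- render_scatter(b, "UMAP", "cluster", tempfile(fileext = ".png"))
  cmap <- b$cells$fields$cluster$color_map
  sizes <- table(unname(s$truth$cluster))
  for (cl in names(cmap)) {
    expect_equal(rep$per_color_counts[[cmap[[cl]]]],
                 as.integer(sizes[[cl]]), label = cl)
  }
})

test_that("an all-zero gene colors every point with the single zero-bin color", {
  d <- tempfile(); dir.create(d)
  em <- sb_matrix(c("gz", "g2"), c("c1", "c2", "c3"),
                  rbind(rep(0, 3), c(1, 2, 3)))
  ct <- sb_cells(c("c1", "c2", "c3"), list(grp = c("a", "b", "a")))
  ly <- sb_layout("L", c("c1", "c2", "c3"), 1:3, 1:3)
  ds <- align_cells(em, ct, list(ly))
  dir.create(file.path(d, "out"))
  st <- build_store(ds$matrix, file.path(d, "out"))
  # assemble a bundle the fast way: build from a config
  writeLines(c("g\tc1\tc2\tc3", "gz\t0\t0\t0", "g2\t1\t2\t3"),
             file.path(d, "expr.tsv"))
  writeLines(c("cell\tgrp", "c1\ta", "c2\tb", "c3\ta"), file.path(d, "meta.tsv"))
  writeLines(c("cell\tx\ty", "c1\t1\t1", "c2\t2\t2", "c3\t3\t3"),
             file.path(d, "coords.tsv"))
  writeLines(c('name="zero"', 'matrix="expr.tsv"', 'meta="meta.tsv"',
               'coords=["coords.tsv:L"]'), file.path(d, "ds.conf"))
  b <- build_dataset(file.path(d, "ds.conf"), file.path(d, "bundle"))
  rep <- render_scatter(b, "L", "gz", tempfile(fileext = ".svg"))
  expect_length(rep$legend, 1)
  expect_equal(rep$legend[[1]]$count, 3)
  expect_length(rep$per_color_counts, 1)
})

test_that("split panes share axis ranges and identical specs give identical reports", {
  b <- syn_small_bundle()
  out <- tempfile(fileext = ".svg")
  rep <- render_split(b, "tSNE", "cluster", "G001", out)
  expect_equal(rep$panes$left$x_range, rep$panes$right$x_range)
  expect_equal(rep$panes$left$y_range, rep$panes$right$y_range)
  expect_equal(rep$panes$left$color_source$kind, "field")
  expect_equal(rep$panes$right$color_source$kind, "gene")

  rep2 <- render_split(b, "tSNE", "cluster", "cluster", tempfile(fileext = ".svg"))
  left <- rep2$panes$left; right <- rep2$panes$right
  expect_identical(left[setdiff(names(left), "figure")],
                   right[setdiff(names(right), "figure")])
})

test_that("split legends agree with the typed field dictionary and legend", {
  s <- syn_small(); b <- syn_small_bundle()
  marker <- s$truth$markers[[1]][1]
  rep <- render_split(b, "tSNE", "cluster", marker, tempfile(fileext = ".svg"))
  f <- b$cells$fields$cluster
  expect_equal(vapply(rep$panes$left$legend, `[[`, "", "label"),
               names(f$value_dict))
  expect_equal(vapply(rep$panes$left$legend, `[[`, "", "color"),
               unname(f$color_map))
  d <- discretize_expression(fetch_gene(b$store, marker),
                             n_bins = b$manifest$bins)
  expect_equal(vapply(rep$panes$right$legend, `[[`, 1L, "count"),
               d$legend$bin_counts)
})

test_that("violin reports pass the comparison statistics through unchanged", {
  s <- syn_small(); b <- syn_small_bundle()
  sel <- select_cells(b$cells, sb_query(pred("cluster", "equals", "cluster_1")))
  vs <- violin_stats(b$store, "G001", sel, b$cells$cell_ids)
  rep <- render_violin(vs, tempfile(fileext = ".svg"))
  expect_equal(rep$groups$selection$mean, vs$group_a$mean)
  expect_equal(rep$groups$selection$q1, vs$group_a$q1)
  expect_equal(rep$groups$background$median, vs$group_b$median)
  expect_equal(rep$groups$selection$cell_count, length(sel))
})

test_that("a one-cell selection renders as a degenerate stick", {
  em <- sb_matrix("g", c("c1", "c2", "c3"), matrix(c(5, 1, 2), 1))
  st <- build_store(em, tempfile())
  vs <- violin_stats(st, "g", "c1", em$cell_ids)
  rep <- render_violin(vs, tempfile(fileext = ".svg"))
  expect_equal(rep$groups$selection$cell_count, 1)
  expect_equal(rep$groups$selection$min, rep$groups$selection$max)
})

test_that("heatmap reports carry the exact per-tile values", {
  b <- syn_small_bundle()
  hm <- cluster_means(b$store, b$cells$fields$cluster, b$cells$cell_ids,
                      b$dataset_genes)
  rep <- render_heatmap(hm, tempfile(fileext = ".svg"))
  expect_equal(rep$cluster_labels, hm$cluster_labels)
  expect_equal(rep$gene_ids, hm$gene_ids)
  for (i in seq_along(hm$cluster_labels)) {
    expect_equal(rep$raw_values[[i]], unname(hm$matrix[i, ]))
    expect_true(all(rep$values[[i]] >= 0 & rep$values[[i]] <= 1))
  }
})

test_that("degenerate heatmaps render: one tile, constant gene scales to zero", {
  em <- sb_matrix(c("g1", "gconst"), c("c1", "c2", "c3"),
                  rbind(c(1, 3, 5), c(2, 2, 2)))
  st <- build_store(em, tempfile())
  f1 <- infer_field_kind("cl", c("only", "only", "only"))
  hm1 <- cluster_means(st, f1, em$cell_ids, "g1")
  rep1 <- render_heatmap(hm1, tempfile(fileext = ".svg"))
  expect_equal(rep1$values[[1]], 0)   # single cluster: constant column
  f2 <- infer_field_kind("cl", c("a", "b", "b"))
  hm2 <- cluster_means(st, f2, em$cell_ids, c("g1", "gconst"))
  rep2 <- render_heatmap(hm2, tempfile(fileext = ".svg"))
  expect_equal(vapply(rep2$values, `[[`, 1, 2), c(0, 0))  # gconst column
})
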