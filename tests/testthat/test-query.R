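# cell selection, export, violin statistics, cluster means

test_that("single equals predicate returns exactly the labeled cells", {
  s <- syn_small(); b <- syn_small_bundle()
  sel <- select_cells(b$cells, sb_query(pred("cluster", "equals", "cluster_2")))
  expect_setequal(sel, names(s$truth$cluster)[s$truth$cluster == "cluster_2"])
})

test_that("an empty predicate list selects all cells (vacuous conjunction)", {
  b <- syn_small_bundle()
  expect_equal(select_cells(b$cells, sb_query()), b$cells$cell_ids)
})

test_that("conjunctive queries match a brute-force row scan on 100 random cases", {
  s <- syn_full()
  ct <- read_annotations(file.path(s$dir, "meta.tsv"))
  fields <- lapply(names(ct$fields), function(nm)
    infer_field_kind(nm, ct$fields[[nm]]))
  names(fields) <- names(ct$fields)
  typed <- sb_cells(ct$cell_ids, fields)
  set.seed(2024)
  for (i in 1:100) {
    q <- random_query(s$truth)
    expect_identical(select_cells(typed, q), brute_force_select(s$truth, q),
                     label = sprintf("query %d", i))
  }
})

test_that("queries on unknown fields or with type mismatches fail loudly", {
  b <- syn_small_bundle()
  expect_error(select_cells(b$cells, sb_query(pred("nope", "equals", "x"))),
               "unknown field 'nope'.*cluster")
  expect_error(select_cells(b$cells, sb_query(pred("cluster", "range", c(1, 2)))),
               "numeric")
  expect_error(pred("age", "range", c(5, 1)), "low <= high")
})

test_that("exported cell lists round-trip in canonical order", {
  b <- syn_small_bundle()
  ids <- b$cells$cell_ids
  f <- tempfile()
  expect_equal(export_cells(character(0), ids, f), 0)
  expect_equal(length(readLines(f)), 0)

  expect_equal(export_cells(ids, ids, f), length(ids))
  expect_equal(readLines(f), ids)

  set.seed(37)
  sel <- sample(ids, 37)
  expect_equal(export_cells(sel, ids, f), 37)
  back <- readLines(f)
  expect_setequal(back, sel)
  expect_equal(back, ids[ids %in% sel])  # canonical order
})

test_that("violin statistics split a simple vector as expected", {
  em <- sb_matrix("g", c("c1", "c2", "c3", "c4"), matrix(c(0, 0, 10, 10), 1))
  st <- build_store(em, tempfile())
  vs <- violin_stats(st, "g", c("c3", "c4"), em$cell_ids)
  expect_equal(vs$group_a$mean, 10)
  expect_equal(vs$group_b$mean, 0)
  expect_equal(vs$group_a$cell_count, 2)
  # selecting everything leaves no background
  expect_error(violin_stats(st, "g", em$cell_ids, em$cell_ids),
               "background group is empty")
})

test_that("selection overlap is removed from the background with a log entry", {
  em <- sb_matrix("g", sprintf("c%d", 1:6), matrix(1:6, 1))
  st <- build_store(em, tempfile())
  vs <- violin_stats(st, "g", c("c1", "c2"), em$cell_ids,
                     background = c("c2", "c3", "c4"))
  expect_equal(vs$group_b$cell_count, 2)
  expect_match(vs$log, "removed 1 cells", all = FALSE)
})

test_that("violin statistics equal a dense recomputation and conserve the mean", {
  s <- syn_small(); b <- syn_small_bundle()
  set.seed(7)
  sel <- sample(b$cells$cell_ids, 100)
  g <- sample(s$truth$gene_symbols, 1)
  vs <- violin_stats(b$store, g, sel, b$cells$cell_ids)
  v <- s$truth$matrix[g, ]
  va <- unname(v[sel]); vb <- unname(v[setdiff(names(v), sel)])
  expect_equal(vs$group_a$mean, mean(va), tolerance = 1e-12)
  expect_equal(vs$group_b$mean, mean(vb), tolerance = 1e-12)
  expect_equal(vs$group_a$median, unname(quantile(va, 0.5, type = 7)))
  expect_equal(vs$group_a$q1, unname(quantile(va, 0.25, type = 7)))
  expect_equal(vs$group_b$q3, unname(quantile(vb, 0.75, type = 7)))
  expect_equal(c(vs$group_a$min, vs$group_a$max), range(va))
  # weighted group means reconstruct the global mean
  na <- vs$group_a$cell_count; nb <- vs$group_b$cell_count
  expect_equal(na + nb, length(v))
  expect_equal((na * vs$group_a$mean + nb * vs$group_b$mean) / (na + nb),
               mean(v), tolerance = 1e-12)
})

test_that("cluster means equal a dense group-by average within 1e-6", {
  s <- syn_small(); b <- syn_small_bundle()
  hm <- cluster_means(b$store, b$cells$fields$cluster, b$cells$cell_ids,
                      b$dataset_genes)
  for (cl in hm$cluster_labels) {
    in_cl <- names(s$truth$cluster)[s$truth$cluster == cl]
    for (g in hm$gene_ids) {
      expect_equal(hm$matrix[cl, g], mean(s$truth$matrix[g, in_cl]),
                   tolerance = 1e-6)
    }
  }
})

test_that("a single cluster reduces the heatmap to global means", {
  em <- sb_matrix(c("g1", "g2"), sprintf("c%d", 1:4),
                  rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)))
  st <- build_store(em, tempfile())
  f <- infer_field_kind("cl", rep("only", 4))
  hm <- cluster_means(st, f, em$cell_ids, c("g1", "g2"))
  expect_equal(unname(hm$matrix["only", ]), c(2.5, 5))
  # constant gene scales to zero under per-gene scaling
  hm2 <- cluster_means(st, f, em$cell_ids, c("g1", "g2"), scaling = "per-gene")
  expect_equal(unname(hm2$matrix[, "g2"]), 0)
})

test_that("unknown heatmap genes are skipped with a warning, not fatal", {
  b <- syn_small_bundle()
  expect_warning(
    hm <- cluster_means(b$store, b$cells$fields$cluster, b$cells$cell_ids,
                        c("G001", "NOPE", "G002")),
    "NOPE")
  expect_equal(hm$gene_ids, c("G001", "G002"))
  expect_error(cluster_means(b$store, b$cells$fields$age, b$cells$cell_ids,
                             "G001"), "categorical")
})

test_that("cluster means are invariant under cell permutation", {
  s <- syn_small()
  em <- read_matrix_dense(file.path(s$dir, "exprMatrix.tsv"))
  set.seed(13)
  perm <- sample(ncol(em$values))
  em2 <- sb_matrix(em$gene_ids, em$cell_ids[perm],
                   em$values[, perm, drop = FALSE])
  st1 <- build_store(em, tempfile())
  st2 <- build_store(em2, tempfile())
  f1 <- infer_field_kind("cl", unname(s$truth$cluster))
  f2 <- infer_field_kind("cl", unname(s$truth$cluster)[perm])
  hm1 <- cluster_means(st1, f1, em$cell_ids, c("G001", "G010"))
  hm2 <- cluster_means(st2, f2, em2$cell_ids, c("G001", "G010"))
  expect_equal(hm1$matrix, hm2$matrix)
})
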