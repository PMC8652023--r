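# Shared fixtures, generated once per test run and memoized. The small
# dataset backs most unit tests; the full-size one backs the end-to-end
# checks that need realistic cluster structure.

.fixtures <- new.env(parent = emptyenv())

syn_small <- function() {
  if (is.null(.fixtures$small)) {
    dir <- file.path(tempdir(), "scbundle-syn-small")
    truth <- generate_dataset(
      synthetic_spec(n_cells = 300L, n_genes = 60L, n_clusters = 3L,
                     markers_per_cluster = 4L, seed = 42L),
      dir)
    .fixtures$small <- list(dir = dir, truth = truth)
  }
  .fixtures$small
}

syn_small_bundle <- function() {
  if (is.null(.fixtures$small_bundle)) {
    s <- syn_small()
    out <- file.path(tempdir(), "scbundle-syn-small-bundle")
    .fixtures$small_bundle <- build_dataset(file.path(s$dir, "dataset.conf"), out)
  }
  .fixtures$small_bundle
}

syn_full <- function() {
  if (is.null(.fixtures$full)) {
    dir <- file.path(tempdir(), "scbundle-syn-full")
    truth <- generate_dataset(synthetic_spec(seed = 1L), dir)
    .fixtures$full <- list(dir = dir, truth = truth)
  }
  .fixtures$full
}

syn_full_bundle <- function() {
  if (is.null(.fixtures$full_bundle)) {
    s <- syn_full()
    out <- file.path(tempdir(), "scbundle-syn-full-bundle")
    .fixtures$full_bundle <- build_dataset(file.path(s$dir, "dataset.conf"), out)
  }
  .fixtures$full_bundle
}

# brute-force selection scan used as the oracle against select_cells()
brute_force_select <- function(truth, q) {
  meta <- data.frame(cluster = unname(truth$cluster),
                     age = unname(truth$age),
                     well = unname(truth$well),
                     stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(truth$cell_ids))
  for (p in q$predicates) {
    v <- meta[[p$field]]
    keep <- keep & switch(p$op,
      equals = as.character(v) == as.character(p$value),
      `in` = as.character(v) %in% as.character(p$value),
      range = as.numeric(v) >= p$value[1] & as.numeric(v) <= p$value[2],
      greater = as.numeric(v) > as.numeric(p$value),
      less = as.numeric(v) < as.numeric(p$value))
  }
  truth$cell_ids[keep]
}

# random conjunctive queries over the synthetic metadata
random_query <- function(truth) {
  n_preds <- sample(1:2, 1)
  preds <- lapply(seq_len(n_preds), function(i) {
    if (runif(1) < 0.5) {
      pred("cluster",
           if (runif(1) < 0.5) "equals" else "in",
           sample(unique(unname(truth$cluster)), sample(1:2, 1)))
    } else {
      lo <- runif(1, 20, 60)
      switch(sample(3, 1),
             pred("age", "range", c(lo, lo + runif(1, 0, 30))),
             pred("age", "greater", lo),
             pred("age", "less", lo))
    }
  })
  do.call(sb_query, preds)
}
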