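# field typing, expression discretization, palettes, histograms

test_that("field kinds classify by parseability and distinctness", {
  expect_equal(infer_field_kind("x", c("1", "2", "2.5"))$kind, "numeric")
  expect_equal(infer_field_kind("x", c("a", "b", "c"))$kind, "uniqueId")
  expect_equal(infer_field_kind("x", c("a", "b", "a"))$kind, "categorical")
  # missing markers do not break numeric classification
  f <- infer_field_kind("x", c("1", "NA", "3"))
  expect_equal(f$kind, "numeric")
  expect_equal(f$values, c(1, NA, 3))
  expect_equal(f$n_missing, 1L)
})

test_that("categorical dictionaries code by descending count with lexicographic ties", {
  set.seed(123)
  labels <- c("alpha", "beta", "gamma", "delta", "eps")
  draws <- sample(labels, 10000, replace = TRUE,
                  prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
  f <- infer_field_kind("cl", draws)
  expect_equal(f$kind, "categorical")
  expect_length(f$value_dict, 5)
  tally <- table(draws)
  expect_equal(unname(f$counts[names(tally)]), unname(as.integer(tally)))
  expect_equal(sum(f$counts), 10000)
  # codes ordered by count descending
  expect_true(all(diff(unname(f$counts[order(f$value_dict)])) <= 0))
  # decoded values round-trip
  expect_equal(names(f$value_dict)[f$values + 1], draws)
})

test_that("missing metadata forms its own category rather than disappearing", {
  f <- infer_field_kind("x", c("a", "", "NA", "a", "b"))
  expect_true("(missing)" %in% names(f$value_dict))
  expect_equal(unname(f$counts["(missing)"]), 2L)
  colored <- assign_colors(f, "classic12")
  expect_equal(unname(colored$color_map["(missing)"]), "#BBBBBB")
})

test_that("zeros get a dedicated first bin and positives split by strategy", {
  d <- discretize_expression(c(0, 0, 0, 5, 5, 5), n_bins = 2)
  expect_true(d$legend$zero_bin)
  expect_equal(d$legend$n_bins, 2L)
  expect_equal(d$legend$bin_counts, c(3L, 3L))
  expect_equal(d$bin, c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("a constant vector collapses to a single logged bin", {
  d <- discretize_expression(c(2, 2, 2), n_bins = 10)
  expect_equal(d$legend$n_bins, 1L)
  expect_equal(d$legend$bin_counts, 3L)
  expect_equal(d$bin, c(0L, 0L, 0L))
  expect_match(d$legend$log, "constant", all = FALSE)
})

test_that("quantile bins match the sort-and-split oracle within one cell", {
  set.seed(21)
  v <- rlnorm(1000, meanlog = 1, sdlog = 1)
  d <- discretize_expression(v, n_bins = 5, strategy = "quantile")
  expect_equal(d$legend$n_bins, 5L)   # no zeros: all 5 bins on positives
  expect_false(d$legend$zero_bin)
  oracle <- floor(seq(0, 1000, length.out = 6))
  oracle_counts <- diff(oracle)
  expect_true(all(abs(d$legend$bin_counts - oracle_counts) <= 1))
  expect_equal(sum(d$legend$bin_counts), 1000)
})

test_that("legend counts conserve cells and bins are monotone in value", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    v <- round(rlnorm(n, 0, 1.5)) * rbinom(n, 1, 0.5)
    nb <- sample(2:10, 1)
    d <- discretize_expression(v, n_bins = nb)
    expect_equal(sum(d$legend$bin_counts), n)
    expect_length(d$legend$bin_counts, d$legend$n_bins)
    # zeros confined to bin 0; monotone: max of bin i <= min of bin i+1
    if (d$legend$zero_bin) expect_true(all(v[d$bin == 0] == 0))
    maxima <- tapply(v, d$bin, max)
    minima <- tapply(v, d$bin, min)
    if (length(maxima) > 1)
      expect_true(all(head(maxima, -1) <= tail(minima, -1)))
    # determinism
    d2 <- discretize_expression(v, n_bins = nb)
    expect_identical(d2$legend$breaks, d$legend$breaks)
  }
})

test_that("tied quantile breaks shrink the bin count with a log entry", {
  v <- c(rep(1, 95), 2, 3, 4, 5, 6)
  d <- discretize_expression(v, n_bins = 10, strategy = "quantile")
  expect_lt(d$legend$n_bins, 10L)
  expect_match(d$legend$log, "shrunk", all = FALSE)
  expect_equal(sum(d$legend$bin_counts), length(v))
})

test_that("categorical colors cycle and expression ramps end at the darkest color", {
  f <- infer_field_kind("x", c("a", "b", "a"))
  colored <- assign_colors(f, "classic12")
  pal <- scbundle:::BUILTIN_PALETTES$classic12
  expect_equal(unname(colored$color_map), pal[1:2], ignore_attr = TRUE)

  f30 <- infer_field_kind("x", rep(sprintf("v%02d", 1:30), each = 2))
  c30 <- assign_colors(f30, "classic12")
  expect_equal(unname(c30$color_map[13]), unname(c30$color_map[1]))

  d <- discretize_expression(c(0, 1, 2, 3, 4, 5), n_bins = 5)
  leg <- assign_colors(d$legend, "whiteRed")
  expect_equal(leg$bin_colors[leg$n_bins], "#67000D")  # darkest ramp endpoint

  expect_error(assign_colors(d$legend, "nope"), "classic12")
})

test_that("field histograms tally the subset and conserve counts", {
  s <- syn_small()
  b <- syn_small_bundle()
  f <- b$cells$fields$cluster
  ids <- b$cells$cell_ids
  # full subset equals the global counts
  expect_equal(field_histogram(f, ids), setNames(as.integer(f$counts), names(f$counts)))
  # empty subset gives zeros
  expect_true(all(field_histogram(f, ids, character(0)) == 0))
  # seeded random subset equals a brute-force tally
  set.seed(17)
  sub <- sample(ids, 120)
  h <- field_histogram(f, ids, sub)
  expect_equal(sum(h), 120)
  truth_tab <- table(factor(unname(s$truth$cluster[sub]), levels = names(h)))
  expect_equal(unname(h), unname(as.integer(truth_tab)))
})
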