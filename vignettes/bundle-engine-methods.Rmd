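---
title: "Inside the bundle engine: formats, binning, queries and the synthetic model"
author: "scbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside the bundle engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbundle)
```

`scbundle` turns a single-cell dataset — expression matrix, cell
annotations, 2D embeddings — into a static directory from which every
browser-style operation can be answered without a compute server. This
vignette documents the design of each component: the assumptions it
makes, the parameters that matter, the numerical conventions it pins
down, and what the synthetic generator does and does not emulate.

## The canonical dataset and cell alignment

All importers converge on the same in-memory model: a gene × cell matrix
with unique text identifiers on both axes, a metadata table keyed by cell
id, and one or more named layouts. Real exports rarely agree perfectly on
their cell sets, so `align_cells()` restricts all sources to their
intersection and fixes the canonical order as the matrix column order
restricted to that intersection. Cells dropped from any source are
counted in the build log; an empty intersection is an error that reports
per-source counts and example ids, because an empty overlap almost always
means mismatched barcode conventions rather than genuinely disjoint data.
Matching is exact string equality by design — fuzzy barcode matching
hides data bugs — with one opt-in normalization, stripping a trailing
`-<digit>` lane suffix (`strip_barcode_suffix()`, the CLI's
`--strip-suffix`).

Two policies worth knowing:

* **Duplicate gene ids** are suffixed `_2`, `_3`, … in input order and
  logged, never summed. Summing silently merges distinct assay rows;
  suffixing keeps every row individually retrievable.
* **Two-column features files** (accession + symbol, the Cellranger
  layout) use the symbol as the display id and keep the accession as an
  alias, because a symbol is what users type into a gene search; both
  resolve to the same stored vector.

Values must be finite and non-negative; negatives are rejected rather
than clamped, since a negative entry in an expression matrix signals an
upstream processing error, not data to be repaired.

## The per-gene store

The store answers one question fast: *give me gene g's vector over all
cells*. Each gene is encoded as little-endian float32, deflate-compressed
(zlib), and appended to `exprMatrix.bin`; the sidecar `exprMatrix.json`
maps gene → `[offset, length, crc32]` and carries an encoding block with
the format version, value type, compression, `n_cells`, and an md5 digest
of the canonical cell-id order. The index lives beside, not inside, the
data file so the data file stays amenable to HTTP range requests. The
digest is re-checked whenever a store is opened against a bundle
manifest, which catches the classic drift bug of a matrix rebuilt after
its metadata.

float32 was chosen over float64 because browser-bound expression values
are display data — the stored value is exactly the float32 rounding of
the input, and the round trip is bit-exact for anything
float32-representable (counts up to 2^24 trivially included). The
optional `uint16` encoding scales each gene to its min/max range; it is
documented as lossy and off by default, correctness before size.

Everything about the store is deterministic: identical input yields
byte-identical output, which upgrades "the build works" to "the build is
reproducible" and makes cross-format equivalence testable at the byte
level.

## Metadata typing and color assignment

Raw metadata columns are text. A column is classified `numeric` when
every non-missing value parses as a number, `uniqueId` when all values
are distinct and non-numeric (per-cell identifiers are not useful as
colors), else `categorical`. Missing markers (`""`, `"NA"`, `"NaN"`)
become `NA` in numeric fields and an explicit `"(missing)"` category —
colored a fixed gray — in categorical ones: missingness should be visible
in a plot, not silently dropped. Categorical codes are assigned in
descending count order with lexicographic tie-breaks, so legends are
stable across runs and the biggest groups take the first palette colors.

Expression coloring discretizes a gene vector into at most `bins` bins
(default 10; tunable per dataset config and per CLI call via `--bins`).
When zeros are present, bin 0 holds exactly the zeros and the remaining
bins partition the positive values — by positive-value quantiles by
default, or equal-width intervals with `strategy = "linear"`. The
quantile default exists because zero-inflated vectors waste most
equal-probability bins on zeros otherwise. Duplicated quantile breaks
(heavy ties) are deduplicated; if that leaves fewer bins, the legend
shrinks and says so in its log, preferring honest bin counts over
fixed-size legends with empty bins. A constant vector degenerates to a
single bin with a logged warning. Invariants the tests enforce: bin
counts sum exactly to the number of cells, every value in bin *i* is ≤
every value in bin *i+1*, and identical inputs give identical breaks.

Palettes are built-in only (two qualitative sets, three sequential
ramps); categorical fields cycle the qualitative set in code order, and
expression legends sample the ramp evenly so the top bin is always the
ramp's darkest endpoint.

## Queries

`select_cells()` evaluates a conjunction of typed predicates — `equals`
and `in` on decoded categorical values, `equals`/`range`/`greater`/`less`
on parsed numbers, `range` closed on both ends. Applying a numeric
operator to a categorical field is an error, not a coercion. Conjunction
is the only combinator because that is what chained interactive filters
mean; disjunction is deliberately out of scope.

`violin_stats()` compares a gene between a selection and either an
explicit background or the rest of the dataset. If a supplied background
overlaps the selection, the overlap is removed from the background and
logged — backgrounds are loose sets in practice — but a background that
ends up empty is an error. Quartiles use linear interpolation (type 7),
recorded in the manifest, because the convention differs across languages
and must be pinned for cross-implementation reproducibility. Values are
reported exactly as stored: whether to log-transform before plotting is
the caller's decision, and the engine does not second-guess it.

`cluster_means()` computes the cluster × genes table of means behind the
heatmap. Genes missing from the store are skipped with a warning rather
than failing the table, because curated dataset-gene lists routinely
mention genes a particular matrix lacks. Per-gene 0–1 scaling maps a
constant row to 0.

## ATAC mode

Peaks are BED-style 0-based half-open intervals, sorted by
(chrom, start, end) with exact duplicates removed and counted; matrix row
names of the form `chrom:start-end` parse to the same records. "Nearby"
is anchored at the transcription start site — `txStart` on the plus
strand, `txEnd − 1` on minus — and a window of *w* bp selects every peak
overlapping the TSS base ± *w* (so *w* = 0 selects exactly the peaks
covering the TSS). The default *w* = 100000 is the conventional
regulatory-proximity radius; it is stored in the manifest and overridable
per query. Lookup is a binary search over sorted starts with a local scan
bounded by the chromosome's maximum peak width, and the tests hold it
equal to an all-pairs overlap scan. Chromosome names match exactly, with
an explicit flag to reconcile the `chr1` / `1` dialects by stripping the
prefix.

## Bundles, manifests, collections

A bundle directory holds the store, gzipped metadata and coordinate
tables, the heatmap TSV, copies of any ATAC files, and a single
`dataset.json` manifest carrying labels, `n_cells`, field dictionaries
with counts and colors, layout list, cluster field, dataset genes, bin
and palette settings, the quartile convention, ATAC parameters, a format
version and the cell-order digest — one fetch bootstraps a viewer. Builds
contain no timestamps and no randomness, so rebuilding unchanged inputs
is byte-identical (the gzip streams are written with a zero mtime).
`validate_bundle()` re-derives the structural invariants — index offsets
contiguous and summing to the file size, sampled genes decoding to
`n_cells` with matching checksums, field counts summing to `n_cells`,
layouts covering the canonical cells, digests agreeing — and reports
findings instead of throwing, since validation exists to describe broken
bundles.

Collections arrange bundles in a tree of named projects: one `index.json`
per internal node, leaves pointing at bundle directories, the whole
hierarchy reconstructible from the root index alone. The tree model is
deliberately minimal (name, label, children/dataset); sibling names must
be unique and leaves must reference built bundles.

## Rendering

The four display types — scatter, split scatter, violin, heatmap — render
to SVG (the deterministic reference) or PNG, but the *tested* surface is
the JSON render report each call writes beside the figure: point counts,
legend entries with per-entry counts, axis ranges, group statistics, tile
values. Pixel output varies with fonts and antialiasing across platforms;
the report does not. Split panes share axis ranges so point positions
correspond between panes, and each pane carries its own legend. Styling
constants (point size 0.6, selection outlined in black at 1.6× size,
default 800×600 px) are documented defaults, not configuration.

## The synthetic generator

Every test input is generated, never downloaded. The model:

* counts: negative binomial with per-gene baseline mean
  `1.5 · exp(N(0, 0.3))` and size 0.25, with an extra dropout probability
  of 0.4 — together ≈ 75–80 % zeros, so the zero-bin discretization path
  is always exercised;
* clusters: 5 near-equal clusters of 1000 cells by default; each cluster
  has 4 marker genes whose mean is multiplied 8-fold in that cluster
  (the dataset-genes list is exactly the marker list, and Fig-1-style
  16-gene heatmaps take the first 16 markers);
* layouts: per-cluster Gaussian blobs (sd 1) around centers on a
  radius-10 circle, rotated differently for the tSNE- and UMAP-named
  layouts; coordinates are rounded to 4 decimals so text serialization is
  lossless;
* metadata: the cluster label, a numeric `age` uniform on [20, 70], and a
  uniqueId `well`;
* ATAC fixture: 500 peaks (widths 200–1000 bp) and 20 gene models over 5
  chromosomes of 10 Mb.

All parameters live in the spec record written beside the data
(`spec.json`), and a fixed seed reproduces every output byte-for-byte,
HDF5 containers included. The generator emulates the *structure* the
engine operates on — sparsity, separable clusters, markers — but not
batch effects, library-size gradients, trajectories, doublets or
ambient RNA; passing tests therefore demonstrate the engine's
correctness on well-formed inputs, not robustness to every artifact of
real data.

Problem sizes used by the test suite and the acceptance script — 1000
cells × 200 genes for the end-to-end checks, 300 × 60 for unit tests, 100
random filter queries, 50 random gene fetches, 500 peaks × 20 genes × 4
windows — were chosen as the smallest sizes at which the sampling
properties under test (marker enrichment in ≥95 % of pairs, blob
separation for ≥90 % of cells) are stable.

## File formats and interop

MTX triples, dense TSV/CSV (delimiter taken from the header line: tab if
present, else comma — a deterministic rule, not a sniffer), AnnData h5ad
and Loom are read natively; h5ad and Loom are written too, with the
AnnData on-disk encoding attributes (`encoding-type`, `_index`,
`column-order`) so Python's anndata reads the output unmodified. The
h5ad reader accepts dense, CSR and CSC matrices, plain and categorical
obs columns, and takes the first two columns of wider embeddings. The
Loom reader requires gene/cell id attributes (erroring with the list of
attributes actually present) and recognizes `<stem>_X/_Y` and
`<stem>1/2` coordinate pairs; an optional `column_order` attribute, which
our writer emits, preserves metadata field order across a round trip.
Seurat's binary `.rds` is intentionally unsupported — both Seurat and
Scanpy export the formats above.

## Known limitations

* The store serves what it was given: no on-the-fly normalization or
  multi-matrix merging.
* One compression/encoding pair per store; the index's format version
  exists so future encodings can coexist.
* Numeric metadata histograms bin over the field's own range with no
  outlier handling.
* Figure styling is fixed; the renderers aim at correctness of the
  mapped data, not publication styling.
* No statistical testing between violin groups — the engine displays
  distributions, it does not test hypotheses.
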