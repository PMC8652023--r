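#' Parse peak identifiers of the form "chrom:start-end"
#'
#' ATAC matrices commonly encode their peaks as row names; this turns them
#' back into interval records (0-based, half-open).
#'
#' @param ids Character vector like `"chr1:100-200"`.
#' @return An `sb_peaks` set, sorted by (chrom, start, end).
#' @export
parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    sb_stop("cannot parse peak id '%s' as chrom:start-end", ids[bad[1L]])
  sb_peaks(vapply(m, `[[`, character(1L), 2L),
           as.numeric(vapply(m, `[[`, character(1L), 3L)),
           as.numeric(vapply(m, `[[`, character(1L), 4L)))
}

# sorted, deduplicated peak set; per-chrom max width cached for the
# bounded-scan overlap query
sb_peaks <- function(chrom, start, end, log = character()) {
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    sb_stop("invalid peak interval %s:%g-%g (start must be < end)",
            chrom[i], start[i], end[i])
  }
  if (any(start < 0)) sb_stop("negative peak start")
  ord <- order(chrom, start, end, method = "radix")
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  dup <- duplicated(paste0(chrom, ":", start, "-", end))
  if (any(dup)) {
    log <- sb_log(log, "deduplicated %d duplicate peak intervals", sum(dup))
    chrom <- chrom[!dup]; start <- start[!dup]; end <- end[!dup]
  }
  max_width <- vapply(split(end - start, chrom), max, numeric(1L))
  structure(list(chrom = chrom, start = start, end = end,
                 peak_id = paste0(chrom, ":", start, "-", end),
                 max_width = max_width, log = log),
            class = "sb_peaks")
}

#' @export
print.sb_peaks <- function(x, ...) {
  cat(sprintf("<sb_peaks> %d peaks on %d chromosome(s)\n",
              length(x$start), length(unique(x$chrom))))
  invisible(x)
}

#' Load ATAC peaks from a BED file
#'
#' BED3+ (0-based, half-open); extra columns are ignored. Peaks are sorted
#' by (chrom, start, end) and exact duplicate intervals are deduplicated
#' with a logged count. Optional chromosome-name normalization maps the
#' "chr1" and "1" dialects onto each other by stripping a leading "chr".
#'
#' @param path BED file, optionally gzipped.
#' @param normalize_chrom If `TRUE`, strip a leading `"chr"` from
#'   chromosome names (do the same to gene models for matching).
#' @return An `sb_peaks` set.
#' @export
load_peaks <- function(path, normalize_chrom = FALSE) {
  dt <- sb_fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 3L) sb_stop("BED file '%s' has %d columns; need >= 3", path, ncol(dt))
  chrom <- as.character(dt[[1L]])
  start <- as.numeric(dt[[2L]])
  end <- as.numeric(dt[[3L]])
  if (anyNA(start) || anyNA(end)) sb_stop("non-numeric coordinates in '%s'", path)
  bad <- which(start >= end)
  if (length(bad))
    sb_stop("invalid interval at line %d of '%s': start %g >= end %g",
            bad[1L], path, start[bad[1L]], end[bad[1L]])
  if (normalize_chrom) chrom <- sub("^chr", "", chrom)
  sb_peaks(chrom, start, end)
}

#' Load gene models from a TSV
#'
#' Columns: symbol, chrom, strand (+/-), txStart, txEnd (0-based,
#' half-open). The transcription start site (TSS) is `txStart` on the plus
#' strand and `txEnd - 1` on the minus strand.
#'
#' @param path Gene model TSV with a header row.
#' @param normalize_chrom Strip a leading `"chr"` from chromosome names.
#' @return A data.frame with columns symbol, chrom, strand, tx_start,
#'   tx_end, tss.
#' @export
load_gene_models <- function(path, normalize_chrom = FALSE) {
  dt <- sb_fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 5L)
    sb_stop("gene model file '%s' needs columns symbol, chrom, strand, txStart, txEnd", path)
  g <- data.frame(symbol = as.character(dt[[1L]]),
                  chrom = as.character(dt[[2L]]),
                  strand = as.character(dt[[3L]]),
                  tx_start = as.numeric(dt[[4L]]),
                  tx_end = as.numeric(dt[[5L]]),
                  stringsAsFactors = FALSE)
  if (!all(g$strand %in% c("+", "-")))
    sb_stop("gene model strand must be '+' or '-'")
  if (any(g$tx_start >= g$tx_end))
    sb_stop("gene model with txStart >= txEnd")
  if (normalize_chrom) g$chrom <- sub("^chr", "", g$chrom)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1)
  g
}

#' Peaks near a gene's transcription start site
#'
#' Returns the peaks overlapping the window `[tss - window, tss + window]`
#' — the TSS base plus `window` bp on each side, so window 0 selects
#' exactly the peaks covering the TSS base — clipped at 0 on the gene's
#' chromosome, using the half-open overlap
#' test `peak.start < query.end && peak.end > query.start`. The lookup is a
#' binary search on the sorted starts plus a bounded local scan (bounded by
#' the chromosome's maximum peak width), not a full scan. The distance is
#' anchored at the TSS — strand-aware — which is the standard
#' regulatory-proximity convention.
#'
#' @param gene One row of [load_gene_models()] output (or a list with
#'   `chrom` and `tss`).
#' @param peaks A sorted `sb_peaks` set.
#' @param window Distance in bp on each side of the TSS (>= 0); default
#'   100000.
#' @return An `sb_peaks` subset in sorted order (possibly empty).
#' @export
peaks_near_gene <- function(gene, peaks, window = 1e5) {
  stopifnot(inherits(peaks, "sb_peaks"), window >= 0)
  qstart <- max(0, gene$tss - window)
  qend <- gene$tss + window + 1
  hits <- overlap_range(peaks, gene$chrom, qstart, qend)
  structure(list(chrom = peaks$chrom[hits], start = peaks$start[hits],
                 end = peaks$end[hits], peak_id = peaks$peak_id[hits],
                 max_width = peaks$max_width, log = character()),
            class = "sb_peaks")
}

# indices of peaks overlapping [qstart, qend) on chrom; binary search on
# start positions, local scan bounded by the chromosome's max peak width
overlap_range <- function(peaks, chrom, qstart, qend) {
  on_chrom <- which(peaks$chrom == chrom)
  if (length(on_chrom) == 0L) return(integer(0))
  starts <- peaks$start[on_chrom]
  # candidates must have start < qend and start > qstart - max_width
  w <- peaks$max_width[[chrom]]
  lo <- findInterval(qstart - w, starts) + 1L     # first start > qstart - w
  hi <- findInterval(qend - 0.5, starts)          # last start < qend
  if (hi < lo) return(integer(0))
  cand <- on_chrom[lo:hi]
  cand[peaks$end[cand] > qstart & peaks$start[cand] < qend]
}
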