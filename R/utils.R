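#' @importFrom stats quantile rnbinom rbinom rnorm runif median setNames
#' @importFrom utils head adist
NULL

# Build logs are plain character vectors carried alongside results; every
# dropped row / shrunk bin / deduplicated id passes through sb_log() so that
# nothing is silently discarded.
sb_log <- function(log, fmt, ...) {
  c(log, sprintf(fmt, ...))
}

sb_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

sb_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

#' Missing-value markers recognised in metadata columns
#' @keywords internal
MISSING_MARKERS <- c("", "NA", "NaN")

is_missing_marker <- function(x) {
  is.na(x) | x %in% MISSING_MARKERS
}

# crc32 of a raw vector, as 8-char lowercase hex
checksum_raw <- function(block) {
  digest::digest(block, algo = "crc32", serialize = FALSE)
}

# digest of the canonical cell order; stored in the matrix-store encoding
# block and the bundle manifest, and compared at open time to detect
# matrix/metadata drift.
cell_order_digest <- function(cell_ids) {
  digest::digest(paste(cell_ids, collapse = "\n"), algo = "md5", serialize = FALSE)
}

# float32 little-endian codec; the store's on-disk value type
encode_f32 <- function(v) {
  writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
}

decode_f32 <- function(bytes) {
  readBin(bytes, what = "numeric", n = length(bytes) %/% 4L,
          size = 4L, endian = "little")
}

# round-trip through float32 without writing (what a fetch will return)
as_f32 <- function(v) decode_f32(encode_f32(v))

# deterministic gzip TSV writer: gzfile() emits mtime = 0 so identical
# content gives identical bytes across runs
write_tsv_gz <- function(dt, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  lines <- c(paste(names(dt), collapse = "\t"),
             do.call(paste, c(lapply(dt, as.character), sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# delimiter rule: tab if the header contains any tab, else comma
detect_delim <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

# fread that handles .gz transparently (decompressed in-process, so no
# optional helper packages are needed)
sb_fread <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    data.table::fread(text = paste(lines, collapse = "\n"), ...)
  } else {
    data.table::fread(path, ...)
  }
}

first_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, n = 1L)
}

# closest ids by edit distance, for "gene not found" messages
closest_ids <- function(x, pool, n = 3L) {
  if (length(pool) == 0L) return(character(0))
  d <- adist(x, pool, ignore.case = TRUE)[1L, ]
  pool[order(d, pool)][seq_len(min(n, length(pool)))]
}
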