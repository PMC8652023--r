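#' Built-in color palettes
#'
#' Two families of palettes are shipped: qualitative sets for categorical
#' metadata fields (colors are cycled in code order when a field has more
#' categories than the palette has colors) and sequential light-to-dark
#' ramps for expression legends (the highest expression bin always receives
#' the darkest ramp endpoint).
#'
#' @format A named list; each entry is a character vector of `#RRGGBB` colors
#'   with a `"type"` attribute of `"qualitative"` or `"sequential"`.
#' @keywords internal
BUILTIN_PALETTES <- local({
  qual <- function(x) structure(x, type = "qualitative")
  seqp <- function(x) structure(x, type = "sequential")
  list(
    # 12-color qualitative set (colorblind-aware, high mutual contrast)
    classic12 = qual(c(
      "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
      "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78")),
    # 20-color qualitative set for deeply clustered datasets
    many20 = qual(c(
      "#1F77B4", "#AEC7E8", "#FF7F0E", "#FFBB78", "#2CA02C", "#98DF8A",
      "#D62728", "#FF9896", "#9467BD", "#C5B0D5", "#8C564B", "#C49C94",
      "#E377C2", "#F7B6D2", "#7F7F7F", "#C7C7C7", "#BCBD22", "#DBDB8D",
      "#17BECF", "#9EDAE5")),
    # light-to-dark-red ramp: the classic expression coloring where cells
    # with higher expression are drawn dark red
    whiteRed = seqp(c("#FFF5F0", "#FCBBA1", "#FB6A4A", "#CB181D", "#67000D")),
    whiteBlue = seqp(c("#F7FBFF", "#C6DBEF", "#6BAED6", "#2171B5", "#08306B")),
    greyViolet = seqp(c("#F7F7F7", "#CBC9E2", "#9E9AC8", "#756BB1", "#54278F"))
  )
})

# color reserved for the "(missing)" category
MISSING_COLOR <- "#BBBBBB"

get_palette <- function(name) {
  if (!name %in% names(BUILTIN_PALETTES)) {
    sb_stop("unknown palette '%s'; available: %s", name,
            paste(names(BUILTIN_PALETTES), collapse = ", "))
  }
  BUILTIN_PALETTES[[name]]
}

# n colors sampled evenly along a sequential ramp; last = darkest endpoint
ramp_colors <- function(palette, n) {
  if (n == 1L) return(palette[length(palette)])
  toupper(grDevices::colorRampPalette(palette)(n))
}
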