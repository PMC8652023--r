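#' Define a collection tree node
#'
#' A collection arranges many built dataset bundles under named projects as
#' a tree: internal nodes carry children, leaves reference a bundle.
#'
#' @param name Directory-safe node name (`[A-Za-z0-9_-]+`).
#' @param short_label Human-readable label (defaults to `name`).
#' @param children List of child `sb_node`s (internal node), or `NULL`.
#' @param dataset Bundle reference for a leaf: the name of a built bundle.
#' @return An `sb_node`.
#' @export
sb_node <- function(name, short_label = name, children = NULL, dataset = NULL) {
  if (!grepl("^[A-Za-z0-9_-]+$", name))
    sb_stop("node name '%s' must match [A-Za-z0-9_-]+", name)
  if (is.null(children) == is.null(dataset))
    sb_stop("node '%s' must have either children or a dataset reference", name)
  structure(list(name = name, short_label = short_label,
                 children = children, dataset = dataset),
            class = "sb_node")
}

# parse the JSON tree document (nested name/shortLabel/children/dataset)
node_from_json <- function(x) {
  kids <- NULL
  if (!is.null(x$children)) kids <- lapply(x$children, node_from_json)
  sb_node(x$name, short_label = x$shortLabel %||% x$name,
          children = kids, dataset = x$dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a collection tree definition (JSON)
#'
#' @param path JSON document with nested `name` / `shortLabel` /
#'   `children` / `dataset` objects.
#' @return The root `sb_node`.
#' @export
read_collection_tree <- function(path) {
  node_from_json(read_json_file(path))
}

#' Assemble a hierarchical collection of built bundles
#'
#' Writes one `index.json` per internal node (in a directory tree
#' mirroring the collection tree); leaf entries point at bundle
#' directories. The whole hierarchy is reconstructible from the root index
#' alone, so a static file server can host many datasets on one instance.
#'
#' @param root Root `sb_node`.
#' @param bundles Named character vector mapping leaf `dataset` references
#'   to built bundle directories.
#' @param out_dir Collection output root.
#' @return `out_dir`, invisibly.
#' @export
build_collection <- function(root, bundles, out_dir) {
  stopifnot(inherits(root, "sb_node"))
  walk <- function(node, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      sb_stop("cannot create collection directory '%s'", dir)
    kid_names <- vapply(node$children, `[[`, character(1L), "name")
    if (anyDuplicated(kid_names))
      sb_stop("duplicate sibling name '%s' under node '%s'",
              kid_names[duplicated(kid_names)][1L], node$name)
    entries <- lapply(node$children, function(ch) {
      if (!is.null(ch$dataset)) {
        bdir <- if (ch$dataset %in% names(bundles)) bundles[[ch$dataset]] else NULL
        if (is.null(bdir) || !file.exists(file.path(bdir, "dataset.json")))
          sb_stop("leaf '%s' references dataset '%s' which is not a built bundle",
                  ch$name, ch$dataset)
        list(name = ch$name, shortLabel = ch$short_label, type = "dataset",
             dataset = ch$dataset, path = bdir)
      } else {
        walk(ch, file.path(dir, ch$name))
        list(name = ch$name, shortLabel = ch$short_label, type = "collection",
             path = ch$name)
      }
    })
    write_json_file(list(format = "scbundle-collection",
                         name = node$name, shortLabel = node$short_label,
                         children = entries),
                    file.path(dir, "index.json"))
  }
  if (is.null(root$children)) sb_stop("collection root must be an internal node")
  walk(root, out_dir)
  invisible(out_dir)
}

#' Reconstruct a collection tree from its root index
#'
#' @param dir Collection root directory (containing `index.json`).
#' @return The root `sb_node`, isomorphic to the tree that built it.
#' @export
read_collection <- function(dir) {
  walk <- function(d) {
    idx <- read_json_file(file.path(d, "index.json"))
    if (!identical(idx$format, "scbundle-collection"))
      sb_stop("'%s' has no collection index", d)
    kids <- lapply(idx$children, function(e) {
      if (identical(e$type, "dataset")) {
        sb_node(e$name, short_label = e$shortLabel, dataset = e$dataset)
      } else {
        sub <- walk(file.path(d, e$path))
        sb_node(e$name, short_label = e$shortLabel, children = sub$children)
      }
    })
    sb_node(idx$name, short_label = idx$shortLabel, children = kids)
  }
  walk(dir)
}
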