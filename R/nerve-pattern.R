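# Traced phrenic nerve skeletons: construction, validation, I/O, transforms.

#' Traced phrenic nerve pattern
#'
#' A rooted tree of 2D points describing one hemidiaphragm's phrenic nerve.
#' The root is the nerve entry point; the two order-1 (primary) branches leave
#' it, with order-2 (secondary) and order-3 (tertiary) branches defasciculating
#' from them towards the motor endplate band.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (micrometres).
#' @param edges data.frame with columns `parent`, `child` (node ids) and
#'   `order` (1 = primary, 2 = secondary, 3 = tertiary).
#' @param entry id of the entry node (tree root).
#' @param side `"left"` or `"right"`.
#' @param scale_um_per_px micrometres per pixel used when rasterizing.
#' @return Object of class `nerve_pattern`.
#' @export
nerve_pattern <- function(nodes, edges, entry, side = c("left", "right"),
                          scale_um_per_px = 1) {
  side <- match.arg(side)
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!all(c("id", "x", "y") %in% names(nodes)))
    phreno_stop("InvalidParams", "`nodes` needs columns id, x, y")
  if (!all(c("parent", "child", "order") %in% names(edges)))
    phreno_stop("InvalidParams", "`edges` needs columns parent, child, order")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    phreno_stop("InvalidParams", "node coordinates must be finite")
  if (anyDuplicated(nodes$id))
    phreno_stop("InvalidParams", "node ids must be unique")
  if (!entry %in% nodes$id)
    phreno_stop("InvalidParams", "entry node %s not among nodes", entry)
  if (!all(edges$parent %in% nodes$id) || !all(edges$child %in% nodes$id))
    phreno_stop("InvalidParams", "edge endpoints must reference node ids")
  # single tree rooted at entry: every non-root node has exactly one parent
  # edge and is reachable from the root
  kids <- edges$child
  if (anyDuplicated(kids) || entry %in% kids)
    phreno_stop("InvalidParams", "graph is not a tree rooted at the entry")
  if (nrow(edges) != nrow(nodes) - 1L)
    phreno_stop("InvalidParams", "tree must have n_nodes - 1 edges")
  # child edge order must not decrease relative to its parent edge
  ord_of_child <- stats::setNames(edges$order, edges$child)
  up <- ord_of_child[as.character(edges$parent)]
  bad <- !is.na(up) & edges$order < up
  if (any(bad))
    phreno_stop("InvalidParams", "branch order decreases along %d edge(s)",
                sum(bad))
  structure(list(nodes = nodes, edges = edges, entry = entry, side = side,
                 scale_um_per_px = scale_um_per_px),
            class = "nerve_pattern")
}

#' @export
print.nerve_pattern <- function(x, ...) {
  cat(sprintf("<nerve_pattern> %s side: %d nodes, %d edges (orders: %s)\n",
              x$side, nrow(x$nodes), nrow(x$edges),
              paste(sort(unique(x$edges$order)), collapse = ",")))
  invisible(x)
}

node_xy <- function(pattern, ids) {
  i <- match(ids, pattern$nodes$id)
  cbind(pattern$nodes$x[i], pattern$nodes$y[i])
}

entry_point <- function(pattern) drop(node_xy(pattern, pattern$entry))

# The two order-1 edges leaving the entry node, error otherwise.
primary_edges_at_entry <- function(pattern) {
  e <- pattern$edges
  prim <- e[e$parent == pattern$entry & e$order == 1L, , drop = FALSE]
  if (nrow(prim) != 2L)
    phreno_stop("NoPrimarySplit",
                "expected exactly 2 primary branches at the entry, found %d",
                nrow(prim))
  prim
}

# Follow the order-1 chain starting with edge (entry -> child), returning the
# ordered node id path.
primary_chain <- function(pattern, first_child) {
  e <- pattern$edges
  path <- c(pattern$entry, first_child)
  cur <- first_child
  repeat {
    nxt <- e$child[e$parent == cur & e$order == 1L]
    if (length(nxt) == 0L) break
    cur <- nxt[1L]
    path <- c(path, cur)
  }
  path
}

#' Rigidly transform a nerve pattern
#'
#' Applies `p -> R p + t` to every node coordinate. All morphometric measures
#' are invariant under this motion when the endplate tangent is transformed
#' alongside.
#'
#' @param pattern a [nerve_pattern()].
#' @param rotation 2x2 rotation matrix (see `rotation_matrix` for degrees).
#' @param translation numeric length-2 offset in micrometres.
#' @return The transformed `nerve_pattern`.
#' @export
transform_pattern <- function(pattern, rotation = diag(2),
                              translation = c(0, 0)) {
  xy <- t(rotation %*% t(cbind(pattern$nodes$x, pattern$nodes$y)))
  pattern$nodes$x <- xy[, 1] + translation[1]
  pattern$nodes$y <- xy[, 2] + translation[2]
  pattern
}

#' Mirror a pattern across the body midline
#'
#' Reflects x to -x and flips the side label. Every morphometric measure is
#' preserved exactly.
#'
#' @param pattern a [nerve_pattern()].
#' @return The mirrored `nerve_pattern`.
#' @export
mirror_pattern <- function(pattern) {
  pattern$nodes$x <- -pattern$nodes$x
  pattern$side <- if (pattern$side == "left") "right" else "left"
  pattern
}

#' Read / write skeleton JSON
#'
#' The on-disk format is
#' `{"nodes":[{"id","x","y"}], "edges":[{"parent","child","order"}],
#'   "entry", "side", "scale_um_per_px"}`.
#'
#' @param path file path.
#' @return `read_pattern_json` returns a [nerve_pattern()];
#'   `write_pattern_json` returns `path` invisibly.
#' @export
read_pattern_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  nerve_pattern(j$nodes, j$edges, j$entry, j$side,
                if (is.null(j$scale_um_per_px)) 1 else j$scale_um_per_px)
}

#' @param pattern a [nerve_pattern()].
#' @rdname read_pattern_json
#' @export
write_pattern_json <- function(pattern, path) {
  jsonlite::write_json(
    list(nodes = pattern$nodes, edges = pattern$edges,
         entry = jsonlite::unbox(pattern$entry),
         side = jsonlite::unbox(pattern$side),
         scale_um_per_px = jsonlite::unbox(pattern$scale_um_per_px)),
    path, digits = NA)
  invisible(path)
}

#' Import an SWC-like skeleton
#'
#' Reads the 7-column SWC layout (`id type x y z radius parent`); the `type`
#' column is taken as the branch order of the edge ending at that node
#' (clamped to 1..3), `z` and `radius` are ignored, and the node whose parent
#' is -1 becomes the entry point.
#'
#' @param path file path to whitespace-delimited SWC text (comments `#`).
#' @param side hemidiaphragm side label.
#' @param scale_um_per_px raster scale to record.
#' @return A [nerve_pattern()].
#' @export
read_swc <- function(path, side = c("left", "right"), scale_um_per_px = 1) {
  side <- match.arg(side)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  root <- tab$id[tab$parent == -1]
  if (length(root) != 1L)
    phreno_stop("InvalidParams", "SWC must have exactly one root (parent -1)")
  hasp <- tab$parent != -1
  edges <- data.frame(parent = tab$parent[hasp], child = tab$id[hasp],
                      order = pmin(3L, pmax(1L, as.integer(tab$type[hasp]))))
  nerve_pattern(tab[, c("id", "x", "y")], edges, root, side, scale_um_per_px)
}

#' Rasterize a nerve pattern and endplate band
#'
#' Draws every edge as a polyline dilated to `width_px`, one mask per branch
#' order, plus the endplate-band mask, so that graph-based and raster-based
#' quantifications can be compared on the same synthetic hemidiaphragm.
#'
#' @param pattern a [nerve_pattern()].
#' @param band an [endplate_band()] (optional; supplies the band mask extent).
#' @param scale micrometres per pixel of the output rasters.
#' @param width_px dilated stroke width in pixels (default 3).
#' @param margin_px padding around the joint bounding box.
#' @return A list with `masks` (named list of logical matrices per order),
#'   `band` (logical matrix or NULL), `entry_px` (0-based x, y of the entry),
#'   `offset_um` (origin of the raster in pattern coordinates), and `scale`.
#' @export
rasterize_pattern <- function(pattern, band = NULL, scale = 1, width_px = 3L,
                              margin_px = 10L) {
  xy <- cbind(pattern$nodes$x, pattern$nodes$y)
  lo <- apply(xy, 2, min); hi <- apply(xy, 2, max)
  if (!is.null(band)) {
    bc <- mask_coordinates(band$mask) * band$scale
    lo <- pmin(lo, apply(bc, 2, min)); hi <- pmax(hi, apply(bc, 2, max))
  }
  off <- floor(lo / scale) - margin_px
  dims <- ceiling(hi / scale) - off + margin_px + 1L
  shape <- c(dims[2], dims[1])  # rows = y extent, cols = x extent
  to_px <- function(p) p / scale - off
  masks <- list()
  for (ord in sort(unique(pattern$edges$order))) {
    m <- matrix(FALSE, shape[1], shape[2])
    sel <- pattern$edges[pattern$edges$order == ord, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      p0 <- to_px(drop(node_xy(pattern, sel$parent[i])))
      p1 <- to_px(drop(node_xy(pattern, sel$child[i])))
      m <- draw_segment(m, p0, p1, scale = 1, width_px = width_px)
    }
    masks[[as.character(ord)]] <- dilate_mask(m, width_px)
  }
  band_px <- NULL
  if (!is.null(band)) {
    band_px <- matrix(FALSE, shape[1], shape[2])
    bc <- round(to_px_coords(mask_coordinates(band$mask) * band$scale, off,
                             scale))
    keep <- bc[, 1] >= 0 & bc[, 2] >= 0 & bc[, 2] < shape[1] &
      bc[, 1] < shape[2]
    band_px[cbind(bc[keep, 2] + 1L, bc[keep, 1] + 1L)] <- TRUE
  }
  list(masks = masks, band = band_px,
       entry_px = to_px(entry_point(pattern)),
       offset_um = off * scale, scale = scale)
}

to_px_coords <- function(p, off, scale) {
  cbind(p[, 1] / scale - off[1], p[, 2] / scale - off[2])
}
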