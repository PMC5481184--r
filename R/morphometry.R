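# Nerve-pattern morphometry: branch crossings, split angle, composite record.

# Counting line parallel to the tangent, at `fraction` of the defasciculation
# distance from the entry point, moving towards the endplate.
counting_line <- function(entry, tangent, fraction = 0.8) {
  d <- defasciculation_distance(entry, tangent)
  if (d <= 0)
    phreno_stop("InvalidParams", "defasciculation distance must be > 0")
  nrm <- line_normal(tangent)
  if (sum((tangent$point - entry) * nrm) < 0) nrm <- -nrm
  line2d(entry + fraction * d * nrm, tangent$direction)
}

# Maximal connected runs of same-order edges: assign every edge of the given
# orders a fascicle id, merging edges that share a node and have equal order.
fascicle_ids <- function(edges) {
  n <- nrow(edges)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nodes <- unique(c(edges$parent, edges$child))
  for (nd in nodes) {
    inc <- which(edges$parent == nd | edges$child == nd)
    if (length(inc) > 1L) {
      for (ord in unique(edges$order[inc])) {
        grp <- inc[edges$order[inc] == ord]
        r <- find(grp[1L])
        for (g in grp[-1L]) parent[find(g)] <- r
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Count branches crossing the counting line
#'
#' Counts the fascicles of the requested branch orders that cross a line
#' parallel to the endplate tangent placed at `fraction` of the
#' defasciculation distance from the nerve entry point, restricted to the
#' span between the extremes of the two primary branches. A fascicle (a
#' connected run of same-order edges) is counted once even if its polyline
#' crosses the line several times.
#'
#' @param pattern a [nerve_pattern()].
#' @param tangent endplate tangent [line2d()].
#' @param fraction position of the counting line along the defasciculation
#'   distance, measured from the entry point (default 0.8).
#' @param orders branch orders counted (default secondary + tertiary).
#' @param gap_tolerance_um crossings of distinct fascicles closer than this
#'   along the line are merged (default 0, no merging).
#' @return Integer crossing count.
#' @export
branch_crossings <- function(pattern, tangent, fraction = 0.8,
                             orders = c(2L, 3L), gap_tolerance_um = 0) {
  primary_edges_at_entry(pattern)  # errors if no 2-way primary split
  cl <- counting_line(entry_point(pattern), tangent, fraction)

  # span between the two order-1 branch extremes, along the line direction
  prim <- pattern$edges[pattern$edges$order == 1L, , drop = FALSE]
  pn <- unique(c(prim$parent, prim$child))
  span <- range(line_coordinate(node_xy(pattern, pn), cl))

  sel <- pattern$edges[pattern$edges$order %in% orders, , drop = FALSE]
  if (nrow(sel) == 0L) return(0L)
  fid <- fascicle_ids(sel)
  ga <- signed_line_distance(node_xy(pattern, sel$parent), cl)
  gb <- signed_line_distance(node_xy(pattern, sel$child), cl)
  ta <- line_coordinate(node_xy(pattern, sel$parent), cl)
  tb <- line_coordinate(node_xy(pattern, sel$child), cl)
  straddle <- ga * gb < 0 | (ga == 0 & gb != 0) | (gb == 0 & ga != 0)
  t_at <- ifelse(ga == gb, ta, ta + ga / (ga - gb) * (tb - ta))
  ok <- straddle & t_at >= span[1] & t_at <= span[2]
  if (!any(ok)) return(0L)
  pos <- tapply(t_at[ok], fid[ok], mean)  # one crossing position per fascicle
  if (gap_tolerance_um > 0 && length(pos) > 1L) {
    pos <- sort(pos)
    return(1L + sum(diff(pos) > gap_tolerance_um))
  }
  length(pos)
}

#' Split angle of the primary branches
#'
#' Angle between the two order-1 branch directions leaving the entry point,
#' each direction averaged over the first (up to) three edges of its chain.
#' The left phrenic nerve splits nearly flat ("T"-like) and the right more
#' acutely ("V"-like).
#'
#' @param pattern a [nerve_pattern()].
#' @param n_edges edges averaged per primary (default 3).
#' @return Angle in degrees, in (0, 180].
#' @export
split_angle <- function(pattern, n_edges = 3L) {
  prim <- primary_edges_at_entry(pattern)
  dirs <- lapply(prim$child, function(ch) {
    path <- primary_chain(pattern, ch)
    k <- min(n_edges, length(path) - 1L)
    v <- c(0, 0)
    for (i in seq_len(k)) {
      seg <- node_xy(pattern, path[i + 1L]) - node_xy(pattern, path[i])
      v <- v + drop(seg) / sqrt(sum(seg^2))
    }
    v / sqrt(sum(v^2))
  })
  d <- max(-1, min(1, sum(dirs[[1]] * dirs[[2]])))
  acos(d) * 180 / pi
}

#' Quantify one hemidiaphragm
#'
#' Composite morphometric record: defasciculation distance, secondary-branch
#' crossing count, primary split angle and endplate-band thickness.
#'
#' @param pattern a [nerve_pattern()].
#' @param band an [endplate_band()].
#' @param fraction counting-line position (see [branch_crossings()]).
#' @param n_bins rectangles for [endplate_thickness()].
#' @param orders branch orders counted at the counting line.
#' @return One-row data.frame with columns `side`,
#'   `defasciculation_distance`, `secondary_branch_count`, `split_angle`,
#'   `endplate_thickness`.
#' @export
quantify_hemidiaphragm <- function(pattern, band, fraction = 0.8,
                                   n_bins = 30L, orders = c(2L, 3L)) {
  axis <- fit_endplate_axis(band)
  data.frame(
    side = pattern$side,
    defasciculation_distance = defasciculation_distance(pattern, axis),
    secondary_branch_count = branch_crossings(pattern, axis, fraction,
                                              orders),
    split_angle = split_angle(pattern),
    endplate_thickness = endplate_thickness(band, n_bins, axis = axis),
    stringsAsFactors = FALSE)
}

#' Right/left ratio summary
#'
#' Per-pair right/left ratios with mean and SEM, the summary used for
#' cross-genotype comparisons of nerve asymmetry. A ratio-of-group-means
#' variant is available but is not the default.
#'
#' @param pairs data.frame (or 2-column matrix) with columns `left` and
#'   `right`, one row per embryo.
#' @param aggregate `"per_pair"` (mean of per-embryo R/L ratios, default) or
#'   `"ratio_of_means"`.
#' @return Object of class `ratio_summary`: `ratios`, `mean`, `sem`, `n`,
#'   `aggregate`.
#' @export
lr_ratio_summary <- function(pairs, aggregate = c("per_pair",
                                                  "ratio_of_means")) {
  aggregate <- match.arg(aggregate)
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$left) || is.null(pairs$right)) {
    names(pairs)[1:2] <- c("left", "right")
  }
  if (nrow(pairs) < 1L)
    phreno_stop("InvalidParams", "need at least one left/right pair")
  if (any(pairs$left <= 0))
    phreno_stop("ZeroDenominator", "left values must be > 0")
  ratios <- pairs$right / pairs$left
  if (aggregate == "per_pair") {
    ms <- mean_sem(ratios)
    out <- list(ratios = ratios, mean = ms$mean, sem = ms$sem,
                n = length(ratios), aggregate = aggregate)
  } else {
    out <- list(ratios = ratios, mean = mean(pairs$right) / mean(pairs$left),
                sem = NA_real_, n = length(ratios), aggregate = aggregate)
  }
  structure(out, class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("<ratio_summary> R/L = %.3f %s (n = %d, %s)\n", x$mean,
              if (is.na(x$sem)) "" else sprintf("+/- %.3f SEM", x$sem),
              x$n, x$aggregate))
  invisible(x)
}

# ---- raster-based quantification -------------------------------------------

#' Count fascicles crossing the counting line on a raster
#'
#' Counts connected foreground components of the requested orders' masks
#' within a 1-pixel band at the counting line, restricted to the span of the
#' primary branches. This is the raster twin of [branch_crossings()].
#'
#' @param rasters output of [rasterize_pattern()] (needs per-order masks and
#'   the band mask).
#' @param fraction counting-line position from the entry point.
#' @param orders branch orders included.
#' @param gap_px pixel gap along the line above which two crossings are
#'   distinct components (default 1.5, 8-connectivity).
#' @return Integer component count.
#' @export
branch_crossings_raster <- function(rasters, fraction = 0.8,
                                    orders = c(2L, 3L), gap_px = 1.5) {
  band <- endplate_band(rasters$band, rasters$scale)
  axis <- fit_endplate_axis(band)
  entry_um <- rasters$entry_px * rasters$scale
  cl <- counting_line(entry_um, axis, fraction)
  keep <- as.character(orders)
  m <- Reduce(`|`, rasters$masks[names(rasters$masks) %in% keep])
  if (is.null(m) || !any(m)) return(0L)
  co <- mask_coordinates(m) * rasters$scale
  g <- signed_line_distance(co, cl)
  onband <- abs(g) <= rasters$scale / 2
  if (!any(onband)) return(0L)
  # primary span from the order-1 mask
  p1 <- rasters$masks[["1"]]
  span <- range(line_coordinate(mask_coordinates(p1) * rasters$scale, cl))
  t_pos <- line_coordinate(co[onband, , drop = FALSE], cl)
  t_pos <- sort(t_pos[t_pos >= span[1] & t_pos <= span[2]])
  if (length(t_pos) == 0L) return(0L)
  1L + sum(diff(t_pos) > gap_px * rasters$scale)
}

#' Quantify a rasterized hemidiaphragm
#'
#' Recovers the morphometric record from binary rasters alone: the tangent is
#' fitted to the band mask, the entry point is taken from the raster
#' metadata, crossings are counted with [branch_crossings_raster()], and the
#' split angle is estimated from the order-1 mask by principal-axis fits to
#' the two arms on either side of the entry.
#'
#' @inheritParams branch_crossings_raster
#' @param side side label carried into the record.
#' @param n_bins rectangles for the thickness measure.
#' @return One-row data.frame matching [quantify_hemidiaphragm()].
#' @export
quantify_raster <- function(rasters, side = "left", fraction = 0.8,
                            n_bins = 30L, orders = c(2L, 3L)) {
  band <- endplate_band(rasters$band, rasters$scale)
  axis <- fit_endplate_axis(band)
  entry_um <- rasters$entry_px * rasters$scale
  p1 <- mask_coordinates(rasters$masks[["1"]]) * rasters$scale
  tpos <- line_coordinate(p1, line2d(entry_um, axis$direction))
  arm_dir <- function(co) {
    cc <- sweep(co, 2, colMeans(co))
    v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
    if (sum((colMeans(co) - entry_um) * v) < 0) v <- -v
    v
  }
  # drop pixels within the dilated entry blob so each arm is clean
  away <- abs(tpos) > 3 * rasters$scale
  d1 <- arm_dir(p1[away & tpos > 0, , drop = FALSE])
  d2 <- arm_dir(p1[away & tpos < 0, , drop = FALSE])
  ang <- acos(max(-1, min(1, sum(d1 * d2)))) * 180 / pi
  data.frame(
    side = side,
    defasciculation_distance = defasciculation_distance(entry_um, axis),
    secondary_branch_count = branch_crossings_raster(rasters, fraction,
                                                     orders),
    split_angle = ang,
    endplate_thickness = endplate_thickness(band, n_bins, axis = axis),
    stringsAsFactors = FALSE)
}
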