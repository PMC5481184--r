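# Motor endplate band: tangent fitting and thickness.

#' Motor endplate band
#'
#' The alpha-bungarotoxin-positive band of acetylcholine-receptor clusters,
#' held as a binary mask. A polygon outline may be given instead and is
#' rasterized.
#'
#' @param mask logical/0-1 matrix, nonzero = foreground.
#' @param scale micrometres per pixel.
#' @param polygon optional two-column matrix of 0-based pixel vertices; used
#'   with `shape` when `mask` is missing.
#' @param shape output dimensions `c(nrow, ncol)` for polygon input.
#' @return Object of class `endplate_band` with fields `mask` and `scale`.
#' @export
endplate_band <- function(mask = NULL, scale = 1, polygon = NULL,
                          shape = NULL) {
  if (is.null(mask)) {
    if (is.null(polygon) || is.null(shape))
      phreno_stop("InvalidParams", "give `mask`, or `polygon` with `shape`")
    mask <- polygon_to_mask(polygon, shape)
  }
  mask <- mask != 0
  if (!any(mask)) phreno_stop("EmptyMask", "endplate mask has no foreground")
  stopifnot_scalar_number(scale, "scale", positive = TRUE)
  structure(list(mask = mask, scale = scale), class = "endplate_band")
}

#' @export
print.endplate_band <- function(x, ...) {
  cat(sprintf("<endplate_band> %d x %d px, %d foreground px, %.3g um/px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$scale))
  invisible(x)
}

#' Fit the tangential axis of the endplate band
#'
#' Total-least-squares fit: the returned line passes through the centroid of
#' the foreground pixels along the major principal axis of their coordinates.
#' This is the straight line traced "tangentially" along the band from which
#' the defasciculation distance is measured.
#'
#' @param band an [endplate_band()].
#' @param min_axis_ratio a meaningful tangent requires an elongated band;
#'   error if sqrt(major/minor eigenvalue) is at or below this ratio.
#' @return A [line2d()] in micrometres.
#' @export
fit_endplate_axis <- function(band, min_axis_ratio = 1.2) {
  co <- mask_coordinates(band$mask) * band$scale
  if (nrow(co) < 2L) phreno_stop("EmptyMask", "endplate mask too small")
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  ratio <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
  if (!is.finite(ratio) || ratio <= min_axis_ratio)
    phreno_stop("DegenerateShape",
                "band is too isotropic for a tangent (axis ratio %.3f <= %.2f)",
                ratio, min_axis_ratio)
  dir <- ev$vectors[, 1]
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  line2d(ctr, dir)
}

#' Defasciculation distance
#'
#' Perpendicular distance (micrometres) from the nerve entry point to the
#' tangential line of the endplate band. This is the distance over which the
#' phrenic nerve defasciculates before reaching the endplates; it is several
#' fold larger on the right hemidiaphragm than on the left.
#'
#' @param entry numeric length-2 entry point (micrometres), or a
#'   [nerve_pattern()] whose entry node is used.
#' @param tangent a [line2d()], usually from [fit_endplate_axis()].
#' @return Distance in micrometres (>= 0).
#' @export
defasciculation_distance <- function(entry, tangent) {
  if (inherits(entry, "nerve_pattern")) entry <- entry_point(entry)
  if (!inherits(tangent, "line2d"))
    phreno_stop("InvalidParams", "`tangent` must be a line2d")
  abs(signed_line_distance(entry, tangent))
}

#' Endplate-band thickness
#'
#' The band is divided into `n_bins` rectangles of equal length along its
#' major axis; the width of each rectangle is the foreground extent
#' perpendicular to the axis, and the mean width is returned. This reproduces
#' the outline-and-30-rectangles procedure used to score the medio-lateral
#' scattering of acetylcholine-receptor clusters.
#'
#' @param band an [endplate_band()].
#' @param n_bins number of rectangles (default 30).
#' @param axis optional precomputed [line2d()]; fitted if missing.
#' @return Mean width in micrometres.
#' @export
endplate_thickness <- function(band, n_bins = 30L, axis = NULL) {
  if (is.null(axis)) axis <- fit_endplate_axis(band)
  co <- mask_coordinates(band$mask) * band$scale
  along <- line_coordinate(co, axis)
  across <- signed_line_distance(co, axis)
  brk <- seq(min(along), max(along), length.out = n_bins + 1L)
  bin <- findInterval(along, brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
  widths <- tapply(across, bin, function(s) max(s) - min(s) + band$scale)
  mean(widths)
}
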