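# 2D geometry primitives shared by the morphometry and raster code.

#' Oriented line in the plane
#'
#' A line through `point` with unit `direction`, used for the tangent of the
#' motor endplate band and for branch-counting lines parallel to it.
#'
#' @param point numeric length-2, a point on the line (micrometres).
#' @param direction numeric length-2; normalised internally, must be nonzero.
#' @return An object of class `line2d` with fields `point` and `direction`
#'   (unit vector).
#' @export
line2d <- function(point, direction) {
  if (length(point) != 2L || !all(is.finite(point)))
    phreno_stop("InvalidParams", "`point` must be two finite coordinates")
  n <- sqrt(sum(direction^2))
  if (length(direction) != 2L || !is.finite(n) || n == 0)
    phreno_stop("InvalidParams", "`direction` must be a nonzero 2-vector")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / n),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> through (%.3f, %.3f), direction (%.4f, %.4f)\n",
              x$point[1], x$point[2], x$direction[1], x$direction[2]))
  invisible(x)
}

# Unit normal, rotated +90 degrees from the direction.
line_normal <- function(line) c(-line$direction[2], line$direction[1])

# Signed perpendicular distance of points (n x 2 matrix or length-2 vector).
signed_line_distance <- function(p, line) {
  p <- matrix(p, ncol = 2L)
  nrm <- line_normal(line)
  (p[, 1] - line$point[1]) * nrm[1] + (p[, 2] - line$point[2]) * nrm[2]
}

# Projection of points onto the line direction (coordinate along the line).
line_coordinate <- function(p, line) {
  p <- matrix(p, ncol = 2L)
  (p[, 1] - line$point[1]) * line$direction[1] +
    (p[, 2] - line$point[2]) * line$direction[2]
}

#' Rotation matrix for an angle in degrees
#'
#' @param theta_deg counter-clockwise rotation angle, degrees.
#' @return 2x2 rotation matrix.
#' @export
rotation_matrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Rigidly transform a line
#'
#' Applies `p -> R p + t` to the line's point and rotates its direction.
#'
#' @param line a [line2d()].
#' @param rotation 2x2 rotation matrix.
#' @param translation numeric length-2 offset.
#' @return The transformed [line2d()].
#' @export
transform_line <- function(line, rotation = diag(2), translation = c(0, 0)) {
  line2d(as.numeric(rotation %*% line$point) + translation,
         as.numeric(rotation %*% line$direction))
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd scanline fill at pixel centres. Vertices are 0-based pixel
#' coordinates (`x = col - 1`, `y = row - 1`).
#'
#' @param vertices two-column matrix or data.frame of polygon vertices (x, y).
#' @param shape integer length-2, output dimensions `c(nrow, ncol)`.
#' @return Logical matrix of dimension `shape`.
#' @export
polygon_to_mask <- function(vertices, shape) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || !all(is.finite(v)))
    phreno_stop("InvalidPolygon", "polygon needs >= 3 finite (x, y) vertices")
  mask <- matrix(FALSE, shape[1], shape[2])
  xs <- v[, 1]; ys <- v[, 2]
  nv <- nrow(v)
  jj <- c(nv, seq_len(nv - 1L))
  for (row in seq_len(shape[1])) {
    y <- row - 1
    # edges straddling this scanline
    cross <- (ys < y & ys[jj] >= y) | (ys[jj] < y & ys >= y)
    if (!any(cross)) next
    xi <- xs[cross] + (y - ys[cross]) /
      (ys[jj][cross] - ys[cross]) * (xs[jj][cross] - xs[cross])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      lo <- ceiling(xi[k]); hi <- floor(xi[k + 1L])
      lo <- max(lo, 0L); hi <- min(hi, shape[2] - 1L)
      if (hi >= lo) mask[row, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

# Foreground pixel centres of a mask as an n x 2 matrix of 0-based (x, y).
mask_coordinates <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Draw a thick segment into a logical matrix (0-based um coords / scale).
draw_segment <- function(mask, p0, p1, scale = 1, width_px = 3L) {
  p0 <- p0 / scale; p1 <- p1 / scale
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len * 4))
  t <- seq(0, 1, length.out = n)
  xs <- round(p0[1] + t * (p1[1] - p0[1]))
  ys <- round(p0[2] + t * (p1[2] - p0[2]))
  keep <- xs >= 0 & ys >= 0 & ys < nrow(mask) & xs < ncol(mask)
  mask[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  if (width_px > 1L) attr(mask, "needs_dilation") <- TRUE
  mask
}

dilate_mask <- function(mask, width_px = 3L) {
  if (width_px <= 1L) return(mask)
  kern <- EBImage::makeBrush(as.integer(width_px), shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask * 1), kern)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}
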