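# Concentric-ring quantification of axon outgrowth from spinal-cord explants.

#' Build concentric ring ROIs around an explant
#'
#' Partitions the image outside the explant border into radial concentric
#' rings of constant spacing, by Euclidean distance to the explant: ring k
#' contains the pixels whose distance to the border lies in
#' `((k-1) * spacing, k * spacing]`. Rings are clipped at the image edge.
#'
#' @param border polygon of the explant border, two-column matrix/data.frame
#'   of 0-based (x, y) pixel vertices, or a logical matrix giving the explant
#'   interior directly.
#' @param spacing ring spacing in pixels (default 25).
#' @param image_shape `c(nrow, ncol)` of the image (ignored when `border` is
#'   a mask).
#' @return Object of class `ring_profile`: `ring_map` (integer matrix, 0 =
#'   explant interior), `dist` (distance-to-border map), `interior`,
#'   `spacing`, `n_rings`, `offsets` (data.frame ring/inner/outer).
#' @export
build_rings <- function(border, spacing = 25, image_shape = NULL) {
  stopifnot_scalar_number(spacing, "spacing", positive = TRUE)
  if (is.matrix(border) && (is.logical(border) ||
                            all(border %in% c(0, 1)))) {
    interior <- border != 0
  } else {
    if (is.null(image_shape))
      phreno_stop("InvalidPolygon", "polygon input needs `image_shape`")
    interior <- polygon_to_mask(border, image_shape)
  }
  if (!any(interior))
    phreno_stop("InvalidPolygon", "explant border encloses no pixels")
  if (all(interior))
    phreno_stop("InvalidPolygon", "explant border covers the whole image")
  dist <- matrix(as.numeric(EBImage::distmap(
    EBImage::Image((!interior) * 1))), nrow(interior), ncol(interior))
  ring_map <- matrix(0L, nrow(dist), ncol(dist))
  outside <- dist > 0
  ring_map[outside] <- as.integer(ceiling(dist[outside] / spacing))
  n_rings <- max(ring_map)
  structure(list(ring_map = ring_map, dist = dist, interior = interior,
                 spacing = spacing, n_rings = n_rings,
                 offsets = data.frame(ring = seq_len(n_rings),
                                      inner = (seq_len(n_rings) - 1) *
                                        spacing,
                                      outer = seq_len(n_rings) * spacing)),
            class = "ring_profile")
}

#' @export
print.ring_profile <- function(x, ...) {
  cat(sprintf("<ring_profile> %d rings, spacing %g px, image %d x %d\n",
              x$n_rings, x$spacing, nrow(x$ring_map), ncol(x$ring_map)))
  invisible(x)
}

#' Total outgrowth area and maximal growth distance
#'
#' Sums the labelled surface of every ring outside the explant and reports
#' the outer offset of the farthest ring containing signal.
#'
#' @param mask binary image of labelled axons, same shape as the profile.
#' @param profile a [ring_profile()] from [build_rings()].
#' @return List with `total_area` (px^2), `max_distance` (px),
#'   `per_ring` (data.frame ring/area).
#' @export
outgrowth_area <- function(mask, profile) {
  mask <- mask != 0
  if (!all(dim(mask) == dim(profile$ring_map)))
    phreno_stop("InvalidParams", "mask and ring profile shapes differ")
  ring <- profile$ring_map
  counts <- tabulate(ring[mask & ring > 0L], nbins = profile$n_rings)
  per_ring <- data.frame(ring = seq_len(profile$n_rings), area = counts)
  occupied <- which(counts > 0)
  list(total_area = sum(counts),
       max_distance = if (length(occupied)) max(occupied) * profile$spacing
                      else 0,
       per_ring = per_ring)
}

# Fascicle widths: run lengths of labelled signal along the iso-distance
# contour at the ring's mid offset. The contour is sampled at uniform
# angular steps around the explant centroid (radial march to the first
# point at the mid offset; assumes a star-shaped explant) and run widths
# accumulate true arc length, which keeps widths unbiased by the pixel
# lattice at any fascicle orientation.
ring_fascicle_widths <- function(mask, profile, ring, step_px = 0.5) {
  mid <- (ring - 0.5) * profile$spacing
  ctr_rc <- colMeans(which(profile$interior, arr.ind = TRUE))
  r_border <- sqrt(sum(profile$interior) / pi)
  n_theta <- max(64L, ceiling(2 * pi * (r_border + mid) / step_px))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r_seq <- seq(1, sqrt(sum(dim(mask)^2)), by = step_px)
  nr <- nrow(mask); nc <- ncol(mask)
  r_at <- rep(NA_real_, n_theta)
  fg <- rep(FALSE, n_theta)
  msk <- mask != 0
  for (i in seq_len(n_theta)) {
    rows <- round(ctr_rc[1] + r_seq * sin(theta[i]))
    cols <- round(ctr_rc[2] + r_seq * cos(theta[i]))
    ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
    if (!any(ok)) next
    dv <- profile$dist[cbind(rows[ok], cols[ok])]
    hit <- which(dv >= mid)
    if (length(hit) == 0L) next
    j <- which(ok)[hit[1L]]
    r_at[i] <- r_seq[j]
    fg[i] <- msk[rows[j], cols[j]]
  }
  if (!any(fg)) return(numeric(0))
  runs <- rle(fg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dtheta <- 2 * pi / n_theta
  widths <- vapply(which(runs$values), function(k) {
    sum(r_at[starts[k]:ends[k]] * dtheta, na.rm = TRUE)
  }, numeric(1))
  # merge a run wrapping across the angular cut
  if (length(widths) > 1L && fg[1L] && fg[n_theta]) {
    widths[1L] <- widths[1L] + widths[length(widths)]
    widths <- widths[-length(widths)]
  }
  widths
}

#' Proximo-distal defasciculation index
#'
#' Ratio of the total fascicle width measured on the proximal ring (second
#' ring by default) to that measured on the distal ring (the first ring whose
#' outer offset exceeds `distal_fraction` of the maximal growth distance).
#' Widths are run lengths of labelled signal along each ring's mid-offset
#' contour. Fascicles that merely split while conserving total width leave
#' the index at ~1; distal widening (or width-preserving branch addition)
#' lowers it below 1, and distal thinning raises it above 1.
#'
#' @inheritParams outgrowth_area
#' @param proximal_ring index of the proximal ring (default 2).
#' @param distal_fraction fraction of the maximal growth distance locating
#'   the distal ring (default 0.3).
#' @return List with `index`, `proximal_ring`, `distal_ring`,
#'   `proximal_widths`, `distal_widths` (pixel run lengths).
#' @export
defasciculation_index <- function(mask, profile, proximal_ring = 2L,
                                  distal_fraction = 0.3) {
  oa <- outgrowth_area(mask, profile)
  if (oa$max_distance <= 0)
    phreno_stop("NoDistalSignal", "no labelled signal outside the explant")
  distal_ring <- min(profile$n_rings,
                     floor(distal_fraction * oa$max_distance /
                             profile$spacing) + 1L)
  pw <- ring_fascicle_widths(mask, profile, proximal_ring)
  dw <- ring_fascicle_widths(mask, profile, distal_ring)
  if (length(pw) == 0L)
    phreno_stop("NoDistalSignal", "proximal ring %d holds no signal",
                proximal_ring)
  if (length(dw) == 0L)
    phreno_stop("NoDistalSignal", "distal ring %d holds no signal",
                distal_ring)
  list(index = sum(pw) / sum(dw), proximal_ring = proximal_ring,
       distal_ring = distal_ring, proximal_widths = pw, distal_widths = dw)
}

#' Outgrowth record for one explant
#'
#' Composite of [outgrowth_area()] and [defasciculation_index()].
#'
#' @inheritParams defasciculation_index
#' @param side explant side label.
#' @return One-row data.frame with `side`, `total_area`, `max_distance`,
#'   `defasciculation_index`.
#' @export
quantify_explant <- function(mask, profile, side = "left",
                             proximal_ring = 2L, distal_fraction = 0.3) {
  oa <- outgrowth_area(mask, profile)
  di <- defasciculation_index(mask, profile, proximal_ring, distal_fraction)
  data.frame(side = side, total_area = oa$total_area,
             max_distance = oa$max_distance,
             defasciculation_index = di$index, stringsAsFactors = FALSE)
}
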