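# Paired-image and per-cell assay quantifiers: RNAscope surface ratios,
# in situ zymography fractions, western-blot pair normalization.

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a fixed-bin histogram. Operates on a
#' plain numeric vector so it can be restricted to the pixels inside a
#' region of interest.
#'
#' @param values numeric intensities.
#' @param n_bins histogram resolution (default 256).
#' @return Threshold value on the scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    phreno_stop("EmptyROI", "no finite intensities to threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  valid <- w0 > 0 & w0 < n
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mtot * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  # the criterion is exactly flat across empty histogram gaps; place the
  # threshold mid-plateau
  top <- which(between >= max(between) * (1 - 1e-9))
  mean(brk[top + 1L])
}

sum_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3L)
    phreno_stop("InvalidParams", "stack must be a matrix or 3D array")
  apply(stack, c(1, 2), sum)
}

roi_mask <- function(roi, shape) {
  if (is.matrix(roi) && all(dim(roi) == shape) &&
      (is.logical(roi) || all(roi %in% c(0, 1)))) return(roi != 0)
  polygon_to_mask(roi, shape)
}

#' RNAscope left/right surface ratio
#'
#' Cross-applied threshold quantification of punctate in situ signal: the
#' threshold is computed (Otsu by default) on the sum projection of the
#' reference side restricted to its ROI, applied identically to both sides,
#' and each side's supra-threshold surface is normalized to its ROI area.
#' Returns the log2 of the right/left surface fractions.
#'
#' @param left_stack,right_stack image stacks (3D arrays, slices along the
#'   third dimension) or single images (matrices).
#' @param left_roi,right_roi ROI polygons (two-column vertices, 0-based
#'   pixels) or logical masks matching the projected image.
#' @param reference side whose projection defines the threshold (default
#'   `"left"`).
#' @param threshold optional fixed threshold overriding the Otsu estimate.
#' @return Object of class `rnascope_result`: `log2_ratio`, `threshold`,
#'   `left_fraction`, `right_fraction`, `reference`, `zero_surface`. A zero
#'   surface on either side yields a +/-Inf `log2_ratio` flagged by
#'   `zero_surface = TRUE` (with a warning), never a silent number.
#' @export
rnascope_lr_ratio <- function(left_stack, right_stack, left_roi, right_roi,
                              reference = c("left", "right"),
                              threshold = NULL) {
  reference <- match.arg(reference)
  lproj <- sum_projection(left_stack)
  rproj <- sum_projection(right_stack)
  lmask <- roi_mask(left_roi, dim(lproj))
  rmask <- roi_mask(right_roi, dim(rproj))
  if (!any(lmask) || !any(rmask))
    phreno_stop("EmptyROI", "both ROIs must contain pixels")
  if (is.null(threshold)) {
    ref_px <- if (reference == "left") lproj[lmask] else rproj[rmask]
    threshold <- otsu_threshold(ref_px)
  }
  lfrac <- sum(lproj[lmask] > threshold) / sum(lmask)
  rfrac <- sum(rproj[rmask] > threshold) / sum(rmask)
  zero <- lfrac == 0 || rfrac == 0
  ratio <- log2(rfrac / lfrac)
  if (zero)
    warning("zero supra-threshold surface on one side; log2 ratio is ",
            ratio, call. = FALSE)
  structure(list(log2_ratio = ratio, threshold = threshold,
                 left_fraction = lfrac, right_fraction = rfrac,
                 reference = reference, zero_surface = zero),
            class = "rnascope_result")
}

#' @export
print.rnascope_result <- function(x, ...) {
  cat(sprintf(
    "<rnascope_result> log2(R/L surface) = %.4f (L %.4f, R %.4f, thr %.4g, ref %s)\n",
    x$log2_ratio, x$left_fraction, x$right_fraction, x$threshold,
    x$reference))
  invisible(x)
}

#' In situ zymography positive fractions
#'
#' Percentage of marker-positive cells (e.g. Islet1/2+ motoneurons) showing
#' gelatinase activity, per side, and the right/left fold change. Cells
#' without the marker never enter the denominator.
#'
#' @param table data.frame with columns `side` (`"left"`/`"right"` or
#'   `"L"`/`"R"`), `marker_positive`, `activity_positive` (logical).
#' @return Object of class `zymography_result`: `per_side` (data.frame with
#'   side, n_marker, n_active, percent) and `fold` (right% / left%).
#' @export
zymography_fraction <- function(table) {
  tab <- as.data.frame(table)
  need <- c("side", "marker_positive", "activity_positive")
  if (!all(need %in% names(tab)))
    phreno_stop("InvalidParams", "`table` needs columns %s",
                paste(need, collapse = ", "))
  tab$side <- ifelse(tab$side %in% c("L", "left"), "left", "right")
  per_side <- do.call(rbind, lapply(c("left", "right"), function(s) {
    g <- tab[tab$side == s, , drop = FALSE]
    nm <- sum(g$marker_positive)
    if (nm == 0L)
      phreno_stop("NoMarkerCells", "no marker-positive cells on the %s side",
                  s)
    na_ <- sum(g$marker_positive & g$activity_positive)
    data.frame(side = s, n_marker = nm, n_active = na_,
               percent = 100 * na_ / nm, stringsAsFactors = FALSE)
  }))
  fold <- per_side$percent[per_side$side == "right"] /
    per_side$percent[per_side$side == "left"]
  structure(list(per_side = per_side, fold = fold),
            class = "zymography_result")
}

#' @export
print.zymography_result <- function(x, ...) {
  cat(sprintf("<zymography_result> left %.2f%%, right %.2f%% (R/L fold %.3g)\n",
              x$per_side$percent[1], x$per_side$percent[2], x$fold))
  invisible(x)
}

#' Normalize western-blot left/right pairs
#'
#' Rescales every replicate so that its left + right sum equals the grand
#' mean of the raw sums, making band intensities comparable across blots
#' while leaving each replicate's right/left ratio untouched.
#'
#' @param replicates data.frame with columns `left` and `right` (band
#'   intensities, already lane-normalized), optionally `replicate` ids.
#' @return data.frame with columns `replicate`, `left`, `right`, `ratio`
#'   (right/left, unchanged by the scaling); the common sum is attached as
#'   attribute `target_sum`.
#' @export
normalize_blot_pairs <- function(replicates) {
  rep_ <- as.data.frame(replicates)
  if (is.null(rep_$left) || is.null(rep_$right))
    phreno_stop("InvalidParams", "`replicates` needs columns left and right")
  if (any(rep_$left < 0 | rep_$right < 0))
    phreno_stop("InvalidParams", "band intensities must be >= 0")
  sums <- rep_$left + rep_$right
  if (any(sums <= 0))
    phreno_stop("ZeroSum", "every replicate needs left + right > 0")
  target <- mean(sums)
  scale <- target / sums
  out <- data.frame(
    replicate = if (is.null(rep_$replicate)) seq_len(nrow(rep_))
                else rep_$replicate,
    left = rep_$left * scale, right = rep_$right * scale)
  out$ratio <- out$right / out$left
  attr(out, "target_sum") <- target
  out
}
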