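# Independent oracles used to validate the package's own implementations.
# Each is a deliberately naive brute-force computation.

# Exact Mann-Whitney p by explicit enumeration of all choose(N, n1) group
# assignments of the pooled values.
oracle_mw_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Exact signed-rank p by explicit enumeration of all 2^n sign assignments.
oracle_wsr_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- signs %*% rk
  p_ge <- mean(ws >= w_obs)
  p_le <- mean(ws <= w_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Raster crossing oracle: label connected components (EBImage::bwlabel) of
# the order-filtered mask restricted to a 1-pixel band at the counting line
# and the primary span, and count the labels.
oracle_band_components <- function(rasters, fraction = 0.8,
                                   orders = c(2L, 3L)) {
  band <- endplate_band(rasters$band, rasters$scale)
  axis <- fit_endplate_axis(band)
  entry_um <- rasters$entry_px * rasters$scale
  d <- defasciculation_distance(entry_um, axis)
  nrm <- c(-axis$direction[2], axis$direction[1])
  if (sum((axis$point - entry_um) * nrm) < 0) nrm <- -nrm
  line_pt <- entry_um + fraction * d * nrm
  m <- Reduce(`|`, rasters$masks[names(rasters$masks) %in%
                                   as.character(orders)])
  if (is.null(m) || !any(m)) return(0L)
  co <- which(m, arr.ind = TRUE)
  xy <- cbind(co[, 2] - 1, co[, 1] - 1) * rasters$scale
  g <- (xy[, 1] - line_pt[1]) * nrm[1] + (xy[, 2] - line_pt[2]) * nrm[2]
  p1 <- which(rasters$masks[["1"]], arr.ind = TRUE)
  p1xy <- cbind(p1[, 2] - 1, p1[, 1] - 1) * rasters$scale
  tau_p1 <- (p1xy[, 1] - line_pt[1]) * axis$direction[1] +
    (p1xy[, 2] - line_pt[2]) * axis$direction[2]
  tau <- (xy[, 1] - line_pt[1]) * axis$direction[1] +
    (xy[, 2] - line_pt[2]) * axis$direction[2]
  keep <- abs(g) <= rasters$scale / 2 & tau >= min(tau_p1) &
    tau <= max(tau_p1)
  band_img <- matrix(0, nrow(m), ncol(m))
  band_img[co[keep, , drop = FALSE]] <- 1
  max(EBImage::bwlabel(EBImage::Image(band_img)))
}

# Per-probe for-loop oracle of the lateralization filter.
oracle_lateralized <- function(em, fold = 1.5, min_embryos = 2L,
                               expression_floor = 200, intensity_floor = 1) {
  embryos <- unique(em$meta$embryo)
  left <- character(0); right <- character(0)
  for (p in rownames(em$expr)) {
    expressed <- TRUE
    for (emb in embryos) {
      cols <- em$meta$sample[em$meta$embryo == emb]
      if (!any(em$calls[p, cols] == "P")) expressed <- FALSE
    }
    if (max(em$expr[p, ]) < expression_floor) expressed <- FALSE
    if (!expressed) next
    lr <- numeric(0)
    for (emb in embryos) {
      l <- max(em$expr[p, em$meta$sample[em$meta$embryo == emb &
                                           em$meta$side == "L"]],
               intensity_floor)
      r <- max(em$expr[p, em$meta$sample[em$meta$embryo == emb &
                                           em$meta$side == "R"]],
               intensity_floor)
      lr <- c(lr, log2(r / l))
    }
    thr <- log2(fold)
    if (all(lr > 0) && mean(lr) > thr && sum(lr > thr) >= min_embryos)
      right <- c(right, p)
    if (all(lr < 0) && mean(lr) < -thr && sum(lr < -thr) >= min_embryos)
      left <- c(left, p)
  }
  list(left = left, right = right)
}

# Hand-built pattern: two horizontal primaries of half-length `half`, with
# vertical secondaries rising from the given x positions to y = top.
toy_pattern <- function(sec_x = numeric(0), half = 100, top = 150,
                        side = "left") {
  nodes <- data.frame(id = 1L, x = 0, y = 0)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      order = integer(0))
  nid <- 1L
  add <- function(x, y, parent, order) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = nid, x = x, y = y))
    edges <<- rbind(edges, data.frame(parent = parent, child = nid,
                                      order = order))
    nid
  }
  for (sgn in c(1, -1)) {
    xs <- sort(sec_x[sign(sec_x) == sgn] * sgn) * sgn
    prev <- 1L
    for (x in xs) {
      at <- add(x, 0, prev, 1L)
      m <- add(x, top / 2, at, 2L)
      add(x, top, m, 2L)
      prev <- at
    }
    add(sgn * half, 0, prev, 1L)
  }
  nerve_pattern(nodes, edges, entry = 1L, side = side)
}

# Random pattern parameters for oracle-equivalence sweeps.
random_pattern_params <- function() {
  pattern_params(
    side = sample(c("left", "right"), 1),
    defasciculation_distance = runif(1, 60, 150),
    n_secondary = sample(0:10, 1),
    split_angle_deg = runif(1, 120, 170),
    endplate_length_um = runif(1, 400, 700),
    endplate_thickness_um = runif(1, 40, 80),
    jitter_sd_um = runif(1, 0, 1),
    seed = sample.int(1e6, 1))
}
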