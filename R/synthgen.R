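# Synthetic-data generators with known ground truth for every input type.

#' Parameters of a synthetic nerve pattern
#'
#' Bundles the generating parameters of one hemidiaphragm. Presets named
#' `"<stage>-<side>"` (e.g. `"E15.5-left"`) carry the measured group means of
#' wild-type embryos at that stage as parameters: defasciculation distances
#' of 77.16/188.51 um and 6/11 secondary branches at E15.5 (left/right),
#' split angles 166/132 degrees, endplate thicknesses 254.9/529.3 um.
#'
#' @param side `"left"` or `"right"`.
#' @param defasciculation_distance um from the entry point to the endplate
#'   tangent.
#' @param n_secondary number of secondary branches (>= 0).
#' @param split_angle_deg angle between the primary branches, in (0, 180].
#' @param endplate_length_um length of the straight endplate band.
#' @param endplate_thickness_um band thickness perpendicular to its axis.
#' @param jitter_sd_um positional jitter applied to every non-entry node.
#' @param seed integer seed recorded in the truth record.
#' @return A validated list of class `pattern_params`.
#' @export
pattern_params <- function(side = c("left", "right"),
                           defasciculation_distance = 77.16,
                           n_secondary = 6L, split_angle_deg = 166,
                           endplate_length_um = 2000,
                           endplate_thickness_um = 254.9,
                           jitter_sd_um = 0, seed = 0L) {
  side <- match.arg(side)
  stopifnot_scalar_number(defasciculation_distance, "defasciculation_distance",
                          positive = TRUE)
  stopifnot_scalar_number(endplate_length_um, "endplate_length_um",
                          positive = TRUE)
  stopifnot_scalar_number(endplate_thickness_um, "endplate_thickness_um",
                          positive = TRUE)
  if (!is.numeric(n_secondary) || n_secondary < 0)
    phreno_stop("InvalidParams", "`n_secondary` must be >= 0")
  if (split_angle_deg <= 0 || split_angle_deg > 180)
    phreno_stop("InvalidParams", "`split_angle_deg` must lie in (0, 180]")
  if (jitter_sd_um < 0)
    phreno_stop("InvalidParams", "`jitter_sd_um` must be >= 0")
  structure(list(side = side,
                 defasciculation_distance = defasciculation_distance,
                 n_secondary = as.integer(n_secondary),
                 split_angle_deg = split_angle_deg,
                 endplate_length_um = endplate_length_um,
                 endplate_thickness_um = endplate_thickness_um,
                 jitter_sd_um = jitter_sd_um, seed = as.integer(seed)),
            class = "pattern_params")
}

#' @param name preset name, `"<stage>-<side>"` with stage in E13.5/E14.5/
#'   E15.5.
#' @rdname pattern_params
#' @export
preset_pattern_params <- function(name, jitter_sd_um = 0, seed = 0L) {
  presets <- list(
    "E13.5-left"  = list(d = 32.76,  n = 6L,  a = 166, t = 254.9),
    "E13.5-right" = list(d = 94.82,  n = 9L,  a = 132, t = 529.3),
    "E14.5-left"  = list(d = 42.56,  n = 8L,  a = 166, t = 254.9),
    "E14.5-right" = list(d = 135.71, n = 11L, a = 132, t = 529.3),
    "E15.5-left"  = list(d = 77.16,  n = 6L,  a = 166, t = 254.9),
    "E15.5-right" = list(d = 188.51, n = 11L, a = 132, t = 529.3))
  if (!name %in% names(presets))
    phreno_stop("InvalidParams", "unknown preset '%s' (have: %s)", name,
                paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  side <- sub("^.*-", "", name)
  pattern_params(side = side, defasciculation_distance = p$d,
                 n_secondary = p$n, split_angle_deg = p$a,
                 endplate_thickness_um = p$t, jitter_sd_um = jitter_sd_um,
                 seed = seed)
}

#' Generate a synthetic hemidiaphragm
#'
#' Builds a nerve pattern and endplate band with known ground truth: the
#' entry point sits at the stated perpendicular distance from a straight
#' band, two primary branches leave it at the stated split angle ("T"-like
#' when flat, "V"-like when acute), and the secondary branches run from the
#' primaries to the band, evenly spaced between the primary extremes with
#' optional positional jitter. Right-sided patterns are the mirrored
#' construction, so a left pattern with the side flipped equals the
#' reflected right-parameterized pattern.
#'
#' @param params a [pattern_params()].
#' @return List with `pattern` ([nerve_pattern()]), `band`
#'   ([endplate_band()]) and `truth` (the generating parameters echoed, with
#'   the frame offsets used).
#' @export
make_nerve_pattern <- function(params) {
  if (!inherits(params, "pattern_params"))
    phreno_stop("InvalidParams", "`params` must come from pattern_params()")
  d <- params$defasciculation_distance
  L <- params$endplate_length_um
  Tk <- params$endplate_thickness_um
  theta <- params$split_angle_deg
  alpha <- (90 - theta / 2) * pi / 180  # primary elevation above horizontal
  # keep secondary attachment points safely below the 80% counting line
  halfspan <- min(L / 4,
                  if (tan(alpha) > 1e-9) 0.64 * d / tan(alpha) else Inf)
  # shift the frame so every coordinate (incl. the band) is >= 0
  ex <- round(L / 2)
  ey <- ceiling(max(0, Tk / 2 - d)) + 2
  band_yc <- ey + d

  n <- params$n_secondary
  m_right <- ceiling(n / 2); m_left <- n - m_right
  att_x <- function(m) if (m == 0L) numeric(0) else halfspan * (seq_len(m) - 0.5) / m
  xr <- att_x(m_right); xl <- -att_x(m_left)

  nodes <- data.frame(id = 1L, x = ex, y = ey)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      order = integer(0))
  nid <- 1L
  add_node <- function(x, y) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = nid, x = x, y = y))
    nid
  }
  # primary chain from the entry through the attachment points to its tip
  add_chain <- function(xs, dir_sign) {
    xs_all <- c(sort(xs, decreasing = dir_sign < 0), dir_sign * halfspan)
    prev <- 1L
    att_ids <- integer(0)
    for (x in xs_all) {
      id <- add_node(ex + x, ey + abs(x) * tan(alpha))
      edges <<- rbind(edges, data.frame(parent = prev, child = id,
                                        order = 1L))
      prev <- id
      if (x %in% xs) att_ids <- c(att_ids, id)
    }
    att_ids
  }
  att_r <- add_chain(xr, 1)
  att_l <- add_chain(xl, -1)
  y_end <- band_yc + Tk / 4
  for (aid in c(att_r, att_l)) {
    ax <- nodes$x[nodes$id == aid]; ay <- nodes$y[nodes$id == aid]
    mid <- add_node(ax, (ay + y_end) / 2)
    tip <- add_node(ax, y_end)
    edges <- rbind(edges,
                   data.frame(parent = c(aid, mid), child = c(mid, tip),
                              order = 2L))
  }
  if (params$jitter_sd_um > 0) {
    withr::with_seed(params$seed, {
      k <- nrow(nodes) - 1L
      nodes$x[-1] <- nodes$x[-1] + rnorm(k, 0, params$jitter_sd_um)
      nodes$y[-1] <- nodes$y[-1] + rnorm(k, 0, params$jitter_sd_um)
    })
  }
  if (params$side == "right") nodes$x <- 2 * ex - nodes$x  # mirror in frame
  pat <- nerve_pattern(nodes, edges, entry = 1L, side = params$side)

  # straight band: rows within thickness/2 of the centreline
  n_rows <- ceiling(band_yc + Tk / 2) + 2L
  mask <- matrix(FALSE, n_rows, round(L) + 1L)
  rows_y <- 0:(n_rows - 1L)
  inband <- abs(rows_y - band_yc) <= Tk / 2 - 0.5
  mask[which(inband), ] <- TRUE
  band <- endplate_band(mask, scale = 1)

  truth <- c(unclass(params),
             list(entry = c(ex, ey), band_centerline_y = band_yc,
                  primary_halfspan = halfspan))
  list(pattern = pat, band = band, truth = truth)
}

# Foreground = pixel centres within `width/2` of the segment p0-p1.
thick_segment_mask <- function(mask, p0, p1, width) {
  h <- width / 2
  lo <- pmax(floor(pmin(p0, p1) - h) - 1, 0)
  hi <- pmin(ceiling(pmax(p0, p1) + h) + 1,
             c(ncol(mask), nrow(mask)) - 1)
  if (any(hi < lo)) return(mask)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- if (len2 == 0) 0 else
    pmax(0, pmin(1, ((px - p0[1]) * v[1] + (py - p0[2]) * v[2]) / len2))
  dx <- px - (p0[1] + t * v[1]); dy <- py - (p0[2] + t * v[2])
  hit <- dx^2 + dy^2 <= h^2
  mask[cbind(py[hit] + 1L, px[hit] + 1L)] <- TRUE
  mask
}

#' Generate a synthetic explant outgrowth image
#'
#' Radial fascicles of constant pixel width grow outward from a circular
#' explant border; a fraction of them bifurcate at `split_at` of the
#' maximal extent (half by default).
#' In `"conserve"` mode the two daughters carry half the parent width (total
#' width conserved); in `"preserve"` mode each daughter keeps the parent
#' width, which raises the distal total width and lowers the
#' proximo-distal index.
#'
#' @param n_fascicles number of radial fascicles (>= 1).
#' @param fascicle_width fascicle width in pixels.
#' @param split_fraction fraction of fascicles that bifurcate, in [0, 1].
#' @param max_extent radial growth beyond the border, pixels.
#' @param seed RNG seed (orients the fascicle fan).
#' @param radius explant border radius in pixels.
#' @param split_mode `"conserve"` or `"preserve"` (see above).
#' @param split_at fraction of `max_extent` at which splitting fascicles
#'   bifurcate (default 0.5).
#' @param divergence_deg angular divergence of each daughter pair.
#' @return List with `mask` (logical matrix), `border` (polygon data.frame
#'   x, y), and `truth`.
#' @export
make_explant_image <- function(n_fascicles = 8L, fascicle_width = 6,
                               split_fraction = 0, max_extent = 150,
                               seed = 0L, radius = 60,
                               split_mode = c("conserve", "preserve"),
                               split_at = 0.5, divergence_deg = 12) {
  split_mode <- match.arg(split_mode)
  if (n_fascicles < 1L)
    phreno_stop("InvalidParams", "`n_fascicles` must be >= 1")
  if (split_fraction < 0 || split_fraction > 1)
    phreno_stop("InvalidParams", "`split_fraction` must lie in [0, 1]")
  stopifnot_scalar_number(fascicle_width, "fascicle_width", positive = TRUE)
  side <- 2 * ceiling(radius + max_extent + 12)
  ctr <- c(side - 1, side - 1) / 2
  mask <- matrix(FALSE, side, side)
  angles <- withr::with_seed(seed, {
    runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n_fascicles) - 1) / n_fascicles
  })
  n_split <- round(split_fraction * n_fascicles)
  dd <- divergence_deg * pi / 180
  at_r <- function(ang, r) ctr + r * c(cos(ang), sin(ang))
  for (i in seq_len(n_fascicles)) {
    a <- angles[i]
    if (i <= n_split) {
      rmid <- radius + split_at * max_extent
      mask <- thick_segment_mask(mask, at_r(a, radius - 2), at_r(a, rmid),
                                 fascicle_width)
      wkid <- if (split_mode == "conserve") fascicle_width / 2
              else fascicle_width
      for (s in c(-1, 1)) {
        tip <- at_r(a, rmid) +
          (radius + max_extent - rmid) * c(cos(a + s * dd), sin(a + s * dd))
        mask <- thick_segment_mask(mask, at_r(a, rmid), tip, wkid)
      }
    } else {
      mask <- thick_segment_mask(mask, at_r(a, radius - 2),
                                 at_r(a, radius + max_extent),
                                 fascicle_width)
    }
  }
  phi <- seq(0, 2 * pi, length.out = 121L)[-121L]
  border <- data.frame(x = ctr[1] + radius * cos(phi),
                       y = ctr[2] + radius * sin(phi))
  truth <- list(n_fascicles = n_fascicles, fascicle_width = fascicle_width,
                split_fraction = split_fraction, max_extent = max_extent,
                radius = radius, split_mode = split_mode,
                split_at = split_at, divergence_deg = divergence_deg,
                seed = seed,
                center = ctr, image_side = side)
  list(mask = mask, border = border, truth = truth)
}

#' Generate a paired left/right expression dataset
#'
#' Emulates the paired laser-capture microarray design: `n_embryos` embryos
#' each contribute one left and one right sample. Baseline intensities are
#' log-normal around 1000; a planted minority of probes is multiplied by
#' `fold` on one side; multiplicative log2-normal noise of standard
#' deviation `noise_sigma_log2` is applied per sample; present calls are
#' `"P"` unless the intensity falls below `call_floor`. Planted probes get
#' baselines of at least 500 so the expressed-transcript gate never hides
#' planted truth.
#'
#' @param n_probes total probes (default 20000).
#' @param n_left_enriched,n_right_enriched planted lateralized probe counts.
#' @param fold planted fold change (> 1).
#' @param noise_sigma_log2 noise SD on the log2 scale.
#' @param n_embryos embryos (default 3).
#' @param call_floor intensities below this are called absent.
#' @param seed RNG seed.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (planted probe ids and parameters).
#' @export
make_expression_dataset <- function(n_probes = 20000L,
                                    n_left_enriched = 146L,
                                    n_right_enriched = 194L, fold = 2,
                                    noise_sigma_log2 = 0.1, n_embryos = 3L,
                                    call_floor = 100, seed = 0L) {
  if (n_left_enriched + n_right_enriched > n_probes)
    phreno_stop("InvalidParams", "planted counts exceed `n_probes`")
  if (fold <= 1) phreno_stop("InvalidParams", "`fold` must be > 1")
  probes <- sprintf("probe%05d", seq_len(n_probes))
  embryos <- paste0("E", seq_len(n_embryos))
  samples <- as.vector(t(outer(embryos, c("L", "R"), paste, sep = "_")))
  meta <- data.frame(sample = samples,
                     embryo = rep(embryos, each = 2L),
                     side = rep(c("L", "R"), n_embryos))
  out <- withr::with_seed(seed, {
    baseline <- rlnorm(n_probes, meanlog = log(1000), sdlog = 1)
    planted <- sample(n_probes, n_left_enriched + n_right_enriched)
    left_ids <- planted[seq_len(n_left_enriched)]
    right_ids <- setdiff(planted, left_ids)
    baseline[planted] <- pmax(baseline[planted], 500)
    expr <- matrix(0, n_probes, length(samples),
                   dimnames = list(probes, samples))
    for (j in seq_along(samples)) {
      mu <- baseline
      if (meta$side[j] == "L") mu[left_ids] <- mu[left_ids] * fold
      else mu[right_ids] <- mu[right_ids] * fold
      noise <- if (noise_sigma_log2 > 0)
        2^rnorm(n_probes, 0, noise_sigma_log2) else 1
      expr[, j] <- mu * noise
    }
    list(expr = expr, left_ids = left_ids, right_ids = right_ids)
  })
  calls <- ifelse(out$expr >= call_floor, "P", "A")
  em <- expression_matrix(out$expr, calls, meta)
  truth <- list(left_enriched = probes[out$left_ids],
                right_enriched = probes[out$right_ids],
                n_probes = n_probes, fold = fold,
                noise_sigma_log2 = noise_sigma_log2,
                n_embryos = n_embryos, call_floor = call_floor, seed = seed)
  list(matrix = em, truth = truth)
}

#' Generate a per-cell zymography assay table
#'
#' Bernoulli marker and activity status per cultured cell; activity is only
#' drawn for marker-positive cells. Defaults calibrate to the measured
#' left/right gelatinase-positive fractions (23.4% vs 37.9%) at the
#' reported culture sizes.
#'
#' @param n_cells_per_side cells per side; length 1 or 2 `(left, right)`.
#' @param p_active_left,p_active_right activity probability among
#'   marker-positive cells.
#' @param p_marker marker (Islet1/2) probability per cell.
#' @param seed RNG seed.
#' @return List with `table` (data.frame side, marker_positive,
#'   activity_positive) and `truth`.
#' @export
make_cell_assay <- function(n_cells_per_side = c(792L, 797L),
                            p_active_left = 0.234, p_active_right = 0.379,
                            p_marker = 1, seed = 0L) {
  for (p in c(p_active_left, p_active_right, p_marker))
    if (p < 0 || p > 1)
      phreno_stop("InvalidParams", "probabilities must lie in [0, 1]")
  n <- rep(as.integer(n_cells_per_side), length.out = 2L)
  tab <- withr::with_seed(seed, {
    do.call(rbind, Map(function(side, ni, pa) {
      marker <- rbinom(ni, 1, p_marker) == 1
      active <- marker & (rbinom(ni, 1, pa) == 1)
      data.frame(side = side, marker_positive = marker,
                 activity_positive = active, stringsAsFactors = FALSE)
    }, c("left", "right"), n, c(p_active_left, p_active_right)))
  })
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(n_cells_per_side = n, p_active_left = p_active_left,
                    p_active_right = p_active_right, p_marker = p_marker,
                    seed = seed))
}

#' Generate western-blot left/right replicates
#'
#' Per-replicate left + right sums vary (uniform on [1, 3]); the right/left
#' ratio is centred on `true_ratio` with multiplicative log-normal noise of
#' coefficient of variation `noise_cv`. With `noise_cv = 0` every replicate
#' carries exactly `true_ratio`.
#'
#' @param n replicates (default 5 blots).
#' @param true_ratio planted right/left ratio (> 0).
#' @param noise_cv multiplicative CV of the ratio.
#' @param seed RNG seed.
#' @return List with `replicates` (data.frame replicate, left, right) and
#'   `truth`.
#' @export
make_blot_replicates <- function(n = 5L, true_ratio = 1.22, noise_cv = 0,
                                 seed = 0L) {
  stopifnot_scalar_number(true_ratio, "true_ratio", positive = TRUE)
  if (noise_cv < 0) phreno_stop("InvalidParams", "`noise_cv` must be >= 0")
  reps <- withr::with_seed(seed, {
    sums <- runif(n, 1, 3)
    ratio <- if (noise_cv > 0)
      true_ratio * exp(rnorm(n, 0, sqrt(log(1 + noise_cv^2)))) else
        rep(true_ratio, n)
    data.frame(replicate = seq_len(n), left = sums / (1 + ratio),
               right = sums * ratio / (1 + ratio))
  })
  list(replicates = reps,
       truth = list(n = n, true_ratio = true_ratio, noise_cv = noise_cv,
                    seed = seed))
}
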