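#' Frangi vesselness of a 2D image
#'
#' Multi-scale Hessian ridge filter for bright tubular structures: at each
#' scale the image is convolved with scale-normalized Gaussian
#' second-derivative kernels, the Hessian eigenvalues are ordered
#' `|l1| <= |l2|`, and vesselness combines the anisotropy ratio `l1/l2`
#' and the second-order structure `S = sqrt(l1^2 + l2^2)`; the response is
#' zero where `l2 > 0` (dark ridges). The maximum over scales is returned.
#'
#' @param img numeric matrix.
#' @param scales Gaussian sigmas in pixels.
#' @param beta anisotropy sensitivity.
#' @param c structure sensitivity; default half the maximum `S` per scale.
#' @return Matrix of vesselness values in `[0, 1)`.
#' @export
frangi_vesselness <- function(img, scales = 1:8, beta = 0.5, c = NULL) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    h <- ceiling(4 * s)
    x <- -h:h
    g <- exp(-x^2 / (2 * s^2)); g <- g / sum(g)
    g1 <- -x / s^2 * g
    g2 <- (x^2 - s^2) / s^4 * g
    Hxx <- s^2 * EBImage::filter2(img, outer(g, g2), boundary = 0)
    Hzz <- s^2 * EBImage::filter2(img, outer(g2, g), boundary = 0)
    Hxz <- s^2 * EBImage::filter2(img, outer(g1, g1), boundary = 0)
    tr2 <- (Hxx + Hzz) / 2
    dd <- sqrt(pmax(((Hxx - Hzz) / 2)^2 + Hxz^2, 0))
    la <- tr2 + dd; lb <- tr2 - dd
    swap <- abs(la) > abs(lb)
    l1 <- ifelse(swap, lb, la)   # |l1| <= |l2|
    l2 <- ifelse(swap, la, lb)
    S2 <- l1^2 + l2^2
    cc <- if (is.null(c)) sqrt(max(S2)) / 2 else c
    if (cc <= 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 > 0] <- 0
    best <- pmax(best, v)
  }
  best
}

# Zhang-Suen binary thinning (vectorized over the full mask)
thin_mask <- function(mask) {
  m <- mask * 1L
  pad <- function(a) rbind(0L, cbind(0L, a, 0L), 0L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1); ci <- 2:(nc + 1)
      P2 <- p[ri - 1, ci]; P3 <- p[ri - 1, ci + 1]; P4 <- p[ri, ci + 1]
      P5 <- p[ri + 1, ci + 1]; P6 <- p[ri + 1, ci]; P7 <- p[ri + 1, ci - 1]
      P8 <- p[ri, ci - 1]; P9 <- p[ri - 1, ci - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (sub == 1)
        del <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      else
        del <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# ordered centerline of a quasi-vertical mask: skeletonize, then take the
# mean lateral position per depth row, lightly smoothed
mask_centerline <- function(mask, grid) {
  fp <- fine_pitch(grid)
  sk <- thin_mask(mask)
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) < 2) idx <- which(mask, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1]))
  xs <- tapply(idx[, 2], idx[, 1], mean)[as.character(rows)]
  if (length(xs) >= 5) {
    k <- min(7L, length(xs) - (1 - length(xs) %% 2))
    if (k >= 3) xs <- stats::filter(xs, rep(1 / k, k), sides = 2) |>
        as.numeric() |> (\(v) ifelse(is.na(v), xs, v))()
  }
  cbind(x_um = (as.numeric(xs) - 0.5) * fp[["x"]],
        z_um = (rows - 0.5) * fp[["z"]])
}

#' Segment vessels from ULM maps
#'
#' Vesselness is computed on `sqrt(mb_flow)` times the speed map normalized
#' to its 99th percentile, binarized with Otsu's threshold and closed with
#' a small disc (sparsely sampled vessels leave sub-pixel gaps along the
#' centerline), and connected components shorter than `min_major_axis_um`
#' along their major axis are dropped. Each remaining component is classified by the flow-weighted
#' mean axial velocity over its mask: descending flow (`v_z > 0`) is an
#' arteriole, ascending flow a venule. The centerline comes from
#' morphological thinning.
#'
#' @param maps an [accumulate_maps()] result.
#' @param min_major_axis_um component length filter (default 500 um).
#' @param scales_px Frangi scales, fine pixels.
#' @param speed_norm_quantile quantile normalizing the speed map.
#' @param closing_px diameter of the disc used to close the binary mask.
#' @return List of `vessel_segment` objects (`mask`, `centerline`, `class`,
#'   `length_um`, `z_range_um`, `mean_vz_mm_s`).
#' @export
segment_vessels <- function(maps, min_major_axis_um = 500,
                            scales_px = c(1, 2, 3, 4, 6, 8),
                            speed_norm_quantile = 0.99, closing_px = 7) {
  flow <- maps$mb_flow; speed <- maps$speed
  if (all(flow == 0)) return(list())
  vn <- quantile(speed[speed > 0], speed_norm_quantile, names = FALSE)
  if (!is.finite(vn) || vn <= 0) vn <- 1
  img <- sqrt(flow) * pmin(speed / vn, 1)
  V <- frangi_vesselness(img, scales_px)
  if (max(V) <= 0) return(list())
  th <- EBImage::otsu(EBImage::Image(V / max(V)), range = c(0, 1)) * max(V)
  bw <- V > th
  if (closing_px > 1)
    bw <- EBImage::closing(EBImage::Image(bw * 1),
                           EBImage::makeBrush(closing_px, "disc")) > 0
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  ft <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(ft))) ft <- matrix(ft, nrow = 1,
                                     dimnames = list(NULL, names(ft)))
  fp <- fine_pitch(maps$grid)
  mean_fp <- mean(fp)
  labm <- as.matrix(EBImage::imageData(lab))
  segs <- list(); sid <- 0L
  for (l in seq_len(nrow(ft))) {
    if (ft[l, "m.majoraxis"] * mean_fp < min_major_axis_um) next
    mask <- labm == l
    w <- flow * mask
    tw <- sum(w)
    if (tw == 0) next
    mean_vz <- sum(maps$vz * w) / tw
    cl <- mask_centerline(mask, maps$grid)
    if (nrow(cl) < 2) next
    sid <- sid + 1L
    segs[[sid]] <- structure(
      list(id = sid, mask = mask, centerline = cl,
           class = if (mean_vz > 0) "arteriole" else "venule",
           length_um = polyline_length(cl),
           z_range_um = range(cl[, "z_um"]),
           mean_vz_mm_s = mean_vz),
      class = "vessel_segment")
  }
  segs
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment #%d> %s, length %.0f um, depth %.0f-%.0f um\n",
              x$id, x$class, x$length_um, x$z_range_um[1], x$z_range_um[2]))
  invisible(x)
}

# sample a map (fine grid) at continuous um positions
sample_map_um <- function(map, grid, x_um, z_um) {
  fp <- fine_pitch(grid)
  bilinear_at(map, z_um / fp[["z"]] + 0.5, x_um / fp[["x"]] + 0.5)
}

centerline_at_depth <- function(centerline, depth_um) {
  x <- approx(centerline[, "z_um"], centerline[, "x_um"], depth_um,
              rule = 2)$y
  dz <- 25
  x1 <- approx(centerline[, "z_um"], centerline[, "x_um"],
               pmin(depth_um + dz, max(centerline[, "z_um"])), rule = 2)$y
  x0 <- approx(centerline[, "z_um"], centerline[, "x_um"],
               pmax(depth_um - dz, min(centerline[, "z_um"])), rule = 2)$y
  tx <- x1 - x0; tz <- pmin(depth_um + dz, max(centerline[, "z_um"])) -
    pmax(depth_um - dz, min(centerline[, "z_um"]))
  nrm <- sqrt(tx^2 + tz^2); nrm[nrm == 0] <- 1
  list(x = x, tangent = cbind(tx / nrm, tz / nrm))
}

#' Longitudinal depth profile of a vessel
#'
#' At each depth a line orthogonal to the local centerline direction samples
#' the speed and flow maps; the profile keeps the speed read at the
#' vessel centre — the flow peak along the line, where the per-pixel mean
#' is estimated from the most marks and is most reliable — and the
#' integrated flow across the line.
#'
#' By default the speed is the magnitude of the per-pixel mean velocity
#' vector rather than the per-pixel mean scalar speed: within a single
#' vessel pixel the flow direction is constant, so the vector mean
#' estimates the same quantity but stays unbiased when the interframe
#' displacement is comparable to the localization noise (the mean of
#' noisy speed magnitudes is biased upward).
#'
#' @param maps an [accumulate_maps()] result.
#' @param segment a `vessel_segment`.
#' @param depth_step_um depth sampling step.
#' @param halfwidth_um half-length of the orthogonal sampling line.
#' @param speed_from `"vector"` (magnitude of the mean velocity) or
#'   `"scalar"` (mean of mark speeds).
#' @return Tibble: `depth_um`, `speed_mm_s` (vessel-centre reading),
#'   `mb_flow` (integral across the line, MBs s^-1 um px^-1).
#' @export
depth_profile <- function(maps, segment, depth_step_um = 50,
                          halfwidth_um = 60,
                          speed_from = c("vector", "scalar")) {
  speed_from <- match.arg(speed_from)
  zr <- segment$z_range_um
  if (diff(zr) <= depth_step_um) abort("centerline spans too few depth steps")
  depths <- seq(zr[1], zr[2], by = depth_step_um)
  fp <- fine_pitch(maps$grid)
  du <- min(fp) / 2
  u <- seq(-halfwidth_um, halfwidth_um, by = du)
  ca <- centerline_at_depth(segment$centerline, depths)
  smap <- if (speed_from == "vector") sqrt(maps$vx^2 + maps$vz^2)
          else maps$speed
  speed <- numeric(length(depths)); flow <- numeric(length(depths))
  for (i in seq_along(depths)) {
    nx <- -ca$tangent[i, 2]; nz <- ca$tangent[i, 1]
    px <- ca$x[i] + u * nx; pz <- depths[i] + u * nz
    sv <- sample_map_um(smap, maps$grid, px, pz)
    fv <- sample_map_um(maps$mb_flow, maps$grid, px, pz)
    speed[i] <- if (any(fv > 0)) sv[which.max(fv)] else 0
    flow[i] <- sum(fv) * du
  }
  tibble(depth_um = depths, speed_mm_s = speed, mb_flow = flow)
}

#' Vessel diameter from a backscatter profile
#'
#' Full width at half maximum of the backscatter profile sampled on a line
#' orthogonal to the vessel at the requested depth. A vessel rasterized
#' onto the fine grid fills whole cells, and reading the map between cell
#' centres turns each edge into a half-cell ramp, so the raw FWHM of a
#' clean lumen is its true width plus one fine pitch; that one-pitch
#' rasterization widening is subtracted. Profiles without a single
#' dominant lobe (all-zero, flat, or with disjoint above-half-max runs)
#' are flagged and carry no value.
#'
#' The profile is the average over `n_lines` parallel orthogonal lines
#' spaced `line_spacing_um` apart along the vessel: single-pixel mean
#' amplitudes fluctuate with the per-bubble echo strength, and a raw
#' single-line maximum would overestimate the half-max reference level.
#'
#' @param backscatter_map matrix on the fine grid (e.g. `maps$backscatter`).
#' @param segment a `vessel_segment`.
#' @param depth_um measurement depth.
#' @param grid a [grid_spec()].
#' @param halfwidth_um half-length of the profile line.
#' @param n_lines number of averaged parallel lines.
#' @param line_spacing_um along-vessel spacing of the lines.
#' @return Tibble: `depth_um`, `diameter_um`, `flagged`, `reason`.
#' @export
measure_diameter <- function(backscatter_map, segment, depth_um, grid,
                             halfwidth_um = 100, n_lines = 5,
                             line_spacing_um = 10) {
  fp <- fine_pitch(grid)
  du <- min(fp) / 4
  u <- seq(-halfwidth_um, halfwidth_um, by = du)
  offs <- (seq_len(n_lines) - (n_lines + 1) / 2) * line_spacing_um
  profs <- vapply(offs, function(o) {
    ca_o <- centerline_at_depth(segment$centerline, depth_um + o)
    nx_o <- -ca_o$tangent[1, 2]; nz_o <- ca_o$tangent[1, 1]
    sample_map_um(backscatter_map, grid,
                  ca_o$x[1] + u * nx_o, depth_um + o + u * nz_o)
  }, numeric(length(u)))
  prof <- rowMeans(profs)
  ca <- centerline_at_depth(segment$centerline, depth_um)
  nx <- -ca$tangent[1, 2]; nz <- ca$tangent[1, 1]
  flag <- function(reason) tibble(depth_um = depth_um,
                                  diameter_um = NA_real_, flagged = TRUE,
                                  reason = reason)
  pk <- max(prof)
  if (pk <= 0) return(flag("empty profile"))
  above <- prof >= pk / 2
  runs <- rle(above)
  if (sum(runs$values) != 1) return(flag("multiple lobes"))
  if (all(above)) return(flag("flat profile (no half-max crossing)"))
  i1 <- which(above)[1]; i2 <- tail(which(above), 1)
  left <- if (i1 == 1) u[1] else {
    f <- (pk / 2 - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
    u[i1 - 1] + f * du
  }
  right <- if (i2 == length(u)) u[length(u)] else {
    f <- (pk / 2 - prof[i2 + 1]) / (prof[i2] - prof[i2 + 1])
    u[i2 + 1] - f * du
  }
  raw <- right - left
  # subtract the one-pitch rasterization widening (projected on the line)
  pitch_line <- abs(nx) * fp[["x"]] + abs(nz) * fp[["z"]]
  tibble(depth_um = depth_um, diameter_um = max(raw - pitch_line, 0),
         flagged = FALSE, reason = NA_character_)
}

#' Vessel tortuosity from the velocity vector field
#'
#' Collects the unit velocity vectors of all qualifying track steps inside
#' the vessel mask (tracks shorter than `min_track_len_um` of path are
#' excluded) and returns the circular standard deviation of their direction
#' angles — zero for straight constant-direction flow, invariant under
#' global rotation and under speed scaling. The variant mode returns the
#' standard deviation of scalar products of consecutive unit vectors along
#' each track.
#'
#' @param segment a `vessel_segment`.
#' @param tracks a `track_set`.
#' @param grid a [grid_spec()].
#' @param min_track_len_um track path-length filter (default 100 um =
#'   0.1 mm).
#' @param roi optional `(x0, z0, width, height)` um rectangle.
#' @param mode `"angle"` (circular sd of angles) or `"scalar"`.
#' @return A `tortuosity_result` tibble row: `value`, `n_vectors`,
#'   `n_tracks`, `mode`.
#' @export
tortuosity <- function(segment, tracks, grid, min_track_len_um = 100,
                       roi = NULL, mode = c("angle", "scalar")) {
  mode <- match.arg(mode)
  steps <- tracks$steps
  len <- tapply(sqrt((steps$x1_um - steps$x0_um)^2 +
                     (steps$z1_um - steps$z0_um)^2), steps$track_id, sum)
  ok_ids <- as.integer(names(len)[len >= min_track_len_um])
  st <- steps[steps$track_id %in% ok_ids, , drop = FALSE]
  if (nrow(st) == 0)
    abort(sprintf("no tracks longer than %g um qualify for tortuosity",
                  min_track_len_um))
  mx <- (st$x0_um + st$x1_um) / 2
  mz <- (st$z0_um + st$z1_um) / 2
  if (!is.null(roi)) {
    inside <- mx >= roi[1] & mx < roi[1] + roi[3] &
      mz >= roi[2] & mz < roi[2] + roi[4]
    st <- st[inside, , drop = FALSE]
    mx <- mx[inside]; mz <- mz[inside]
  }
  if (!is.null(segment$mask)) {
    fp <- fine_pitch(grid)
    r <- pmin(pmax(floor(mz / fp[["z"]]) + 1, 1), nrow(segment$mask))
    cc <- pmin(pmax(floor(mx / fp[["x"]]) + 1, 1), ncol(segment$mask))
    st <- st[segment$mask[cbind(r, cc)], , drop = FALSE]
  }
  st <- st[st$speed_mm_s > 0, , drop = FALSE]
  if (nrow(st) == 0)
    abort("no qualifying track steps inside the vessel mask")
  ux <- st$vx_mm_s / st$speed_mm_s
  uz <- st$vz_mm_s / st$speed_mm_s
  if (mode == "angle") {
    theta <- atan2(uz, ux)
    R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
    val <- sqrt(pmax(-2 * log(R), 0))
  } else {
    st <- arrange(st, .data$track_id, .data$frame)
    same <- st$track_id == lead(st$track_id, default = -1L)
    i <- which(same)
    if (!length(i)) abort("not enough consecutive steps for scalar mode")
    dots <- ux[i] * ux[i + 1] + uz[i] * uz[i + 1]
    val <- sd(dots)
  }
  structure(tibble(value = val, n_vectors = nrow(st),
                   n_tracks = length(unique(st$track_id)), mode = mode),
            class = c("tortuosity_result", class(tibble())))
}

#' Roundness of a segmented region
#'
#' `4 * area / (pi * major_axis^2)`; 1 for a disc, `b/a` for an ellipse
#' with full axes `a > b`.
#'
#' @param area_um2 region area.
#' @param major_axis_um major axis length.
#' @return Dimensionless roundness in `(0, 1]`.
#' @export
roundness <- function(area_um2, major_axis_um) {
  if (any(area_um2 <= 0) || any(major_axis_um <= 0))
    abort("area and major axis must be positive")
  4 * area_um2 / (pi * major_axis_um^2)
}
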