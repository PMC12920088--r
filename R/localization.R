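#' Lanczos interpolation
#'
#' Separable Lanczos (a = 3) upsampling used to refine frames before
#' microbubble detection. Output node `j` (0-based) sits at input coordinate
#' `j / factor`, so values at original nodes are preserved.
#'
#' @param frame numeric matrix.
#' @param factor integer upsampling factor (>= 1).
#' @param a Lanczos kernel support.
#' @return The upsampled matrix, `factor` times larger in each dimension.
#' @export
interpolate_frame <- function(frame, factor, a = 3) {
  if (factor < 1) abort("interpolation factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  Wz <- lanczos_matrix(nrow(frame), factor, a)
  Wx <- lanczos_matrix(ncol(frame), factor, a)
  Wz %*% frame %*% t(Wx)
}

lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  core <- abs(x) < a & x != 0
  out[x == 0] <- 1
  xi <- x[core]
  out[core] <- a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2)
  out
}

lanczos_matrix <- function(n_in, factor, a = 3) {
  n_out <- n_in * factor
  xj <- (seq_len(n_out) - 1L) / factor   # position in input node units
  i <- pmax(0L, ceiling(xj - a))
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- max(0L, ceiling(xj[j] - a)); hi <- min(n_in - 1L, floor(xj[j] + a))
    idx <- lo:hi
    w <- lanczos_kernel(xj[j] - idx, a)
    W[j, idx + 1L] <- w / sum(w)   # renormalize truncated kernels
  }
  W
}

gaussian_template <- function(sigma_px, halfwidth_sd = 3) {
  if (length(sigma_px) == 1) sigma_px <- c(sigma_px, sigma_px)
  hz <- ceiling(halfwidth_sd * sigma_px[1]); hx <- ceiling(halfwidth_sd * sigma_px[2])
  z <- -hz:hz; x <- -hx:hx
  outer(exp(-z^2 / (2 * sigma_px[1]^2)), exp(-x^2 / (2 * sigma_px[2]^2)))
}

# zero-normalized cross-correlation of each frame of a 3D array (or a
# matrix) with a template; returns an array of the same shape
zncc <- function(frames, template) {
  mat <- is.matrix(frames)
  if (mat) frames <- array(frames, c(dim(frames), 1L))
  tc <- template - mean(template)
  ss_t <- sum(tc^2)
  n <- length(template)
  ones <- matrix(1, nrow(template), ncol(template))
  num <- EBImage::filter2(frames, tc, boundary = 0)
  s1 <- EBImage::filter2(frames, ones, boundary = 0)
  s2 <- EBImage::filter2(frames^2, ones, boundary = 0)
  varf <- pmax(s2 - s1^2 / n, 0)
  den <- sqrt(varf * ss_t)
  corr <- num / den
  corr[den < 1e-9 * max(den)] <- 0
  corr[!is.finite(corr)] <- 0
  corr <- pmin(pmax(corr, -1), 1)
  if (mat && length(dim(corr)) == 3) corr <- corr[, , 1]
  corr
}

# strict/tie-broken 8-neighbourhood local maxima of each frame of a 3D
# array; returns a logical array (borders FALSE)
local_maxima <- function(a) {
  d <- dim(a); nr <- d[1]; nc <- d[2]
  res <- array(FALSE, d)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- a[ri, ci, , drop = FALSE]
  ok <- array(TRUE, dim(ctr))
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    nb <- a[ri + dz, ci + dx, , drop = FALSE]
    # ties broken toward the lexicographically earlier pixel
    if (dz > 0 || (dz == 0 && dx > 0)) ok <- ok & (ctr > nb)
    else ok <- ok & (ctr >= nb)
  }
  res[ri, ci, ] <- ok
  res
}

#' Detect microbubbles in an interpolated frame
#'
#' Correlates the frame with a unit Gaussian point-spread template
#' (zero-normalized cross-correlation, window +-3 sigma), keeps
#' 8-neighbourhood local maxima above `corr_threshold`, and reduces maxima
#' closer than one PSF full width at half maximum to the most intense one.
#'
#' @param frame_interp interpolated frame (matrix).
#' @param psf_sigma_px Gaussian PSF sigma in interpolated pixels
#'   (scalar or `(z, x)`).
#' @param corr_threshold minimum correlation (detections with correlation
#'   at or below it are rejected).
#' @return Tibble of coarse detections: `row`, `col` (1-based pixel),
#'   `corr`.
#' @export
detect_mbs <- function(frame_interp, psf_sigma_px, corr_threshold = 0.7) {
  if (length(psf_sigma_px) == 1) psf_sigma_px <- rep(psf_sigma_px, 2)
  stopifnot(all(psf_sigma_px > 0), corr_threshold > 0, corr_threshold < 1)
  tmpl <- gaussian_template(psf_sigma_px)
  corr <- zncc(frame_interp, tmpl)
  hw <- max(ceiling(3 * psf_sigma_px))
  peaks_from_corr(corr, corr_threshold, hw,
                  fwhm_px = 2.3548 * mean(psf_sigma_px))
}

peaks_from_corr <- function(corr, threshold, border, fwhm_px) {
  lm <- local_maxima(array(corr, c(dim(corr)[1:2], 1L)))[, , 1]
  lm[corr <= threshold] <- FALSE
  nr <- nrow(corr); nc <- ncol(corr)
  lm[seq_len(min(border, nr)), ] <- FALSE
  lm[max(1, nr - border + 1):nr, ] <- FALSE
  lm[, seq_len(min(border, nc))] <- FALSE
  lm[, max(1, nc - border + 1):nc] <- FALSE
  idx <- which(lm, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(tibble(row = integer(), col = integer(), corr = numeric()))
  pk <- tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
               corr = corr[idx])
  nms_peaks(pk, fwhm_px)
}

# non-maximum suppression: greedy by intensity, suppress within one FWHM;
# returns the indices (into the input order) that survive
nms_keep <- function(rows, cols, corr, fwhm_px) {
  ord <- order(-corr, rows, cols)
  keep <- rep(TRUE, length(ord))
  for (ii in seq_along(ord)) {
    if (!keep[ii]) next
    later <- which(keep & seq_along(ord) > ii)
    if (!length(later)) break
    d2 <- (rows[ord[later]] - rows[ord[ii]])^2 +
      (cols[ord[later]] - cols[ord[ii]])^2
    keep[later[d2 < fwhm_px^2]] <- FALSE
  }
  sort(ord[keep])
}

nms_peaks <- function(pk, fwhm_px) {
  pk[nms_keep(pk$row, pk$col, pk$corr, fwhm_px), ]
}

# sidelobe rejection: order peaks by amplitude; a weaker peak within
# `radius_px` of a kept stronger peak survives only if its amplitude is at
# least `ratio` of the stronger one
sidelobe_keep <- function(rows, cols, amp, radius_px, ratio) {
  ord <- order(-amp)
  keep <- rep(TRUE, length(ord))
  for (ii in seq_along(ord)) {
    if (!keep[ii]) next
    later <- which(keep & seq_along(ord) > ii)
    if (!length(later)) break
    d2 <- (rows[ord[later]] - rows[ord[ii]])^2 +
      (cols[ord[later]] - cols[ord[ii]])^2
    weak <- amp[ord[later]] < ratio * amp[ord[ii]]
    keep[later[d2 < radius_px^2 & weak]] <- FALSE
  }
  sort(ord[keep])
}

quad_pinv <- local({
  g <- expand.grid(x = -1:1, y = -1:1)
  X <- with(g, cbind(1, x, y, x^2, y^2, x * y))
  solve(crossprod(X)) %*% t(X)   # 6 x 9; value order: y fast within x? see gather
})

# vectorized 2D quadratic refinement from gathered 3x3 neighbourhoods
# (columns ordered dx fast within dy, matching expand.grid(x, y))
refine_from_neigh <- function(F9) {
  cf <- F9 %*% t(quad_pinv)
  bx <- cf[, 2]; by <- cf[, 3]; axx <- cf[, 4]; ayy <- cf[, 5]; axy <- cf[, 6]
  det <- 4 * axx * ayy - axy^2
  concave <- axx < 0 & det > 0
  dx <- ifelse(concave, (-2 * ayy * bx + axy * by) / det, 0)
  dy <- ifelse(concave, (-2 * axx * by + axy * bx) / det, 0)
  flagged <- !concave
  clamp <- function(v) pmin(pmax(v, -0.5), 0.5)
  list(drow = unname(clamp(dy)), dcol = unname(clamp(dx)),
       flagged = unname(flagged))
}

# gather 3x3 neighbourhoods of 1-based integer peaks and refine
refine_peaks <- function(map, rows, cols) {
  n <- length(rows)
  F9 <- matrix(0, n, 9)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {   # dx fast within dy
    k <- k + 1L
    F9[, k] <- map[cbind(rows + dy, cols + dx)]
  }
  refine_from_neigh(F9)
}

#' Subpixel refinement of a correlation peak
#'
#' Fits a 2D second-order polynomial to the 3x3 neighbourhood of an integer
#' peak and returns its stationary point; offsets are clamped to +-0.5 px.
#' Non-concave fits fall back to the integer position and are flagged.
#'
#' @param corr_map correlation map (matrix).
#' @param peak integer `(row, col)` of the peak (1-based, not on the border).
#' @return A list with `row`, `col` (continuous), `drow`, `dcol`, `flagged`.
#' @export
refine_subpixel <- function(corr_map, peak) {
  r <- peak[1]; c <- peak[2]
  if (r <= 1 || c <= 1 || r >= nrow(corr_map) || c >= ncol(corr_map))
    abort("peak lies on the map border")
  rf <- refine_peaks(corr_map, r, c)
  list(row = unname(r + rf$drow), col = unname(c + rf$dcol),
       drow = rf$drow, dcol = rf$dcol, flagged = rf$flagged)
}

bilinear_at <- function(mat, r, c) {
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    mat[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Registered backscatter amplitude
#'
#' Magnitude of the filtered frame interpolated at a subpixel position
#' with a separable Lanczos (a = 3) kernel, matching the pipeline's
#' spatial interpolation.
#'
#' @param frame filtered (interpolated) frame, matrix.
#' @param row,col continuous 1-based position.
#' @return Amplitude (linear, arbitrary units).
#' @export
register_backscatter <- function(frame, row, col) {
  lanczos_at(abs(frame), row, col)
}

# separable Lanczos-3 interpolation of a matrix at continuous 1-based
# positions (vectorized over points)
lanczos_at <- function(mat, r, c) {
  nr <- nrow(mat); nc <- ncol(mat)
  vapply(seq_along(r), function(i) {
    ri <- min(max(r[i], 1), nr); ci <- min(max(c[i], 1), nc)
    r0 <- max(1, floor(ri) - 2):min(nr, floor(ri) + 3)
    c0 <- max(1, floor(ci) - 2):min(nc, floor(ci) + 3)
    wr <- lanczos_kernel(ri - r0); wr <- wr / sum(wr)
    wc <- lanczos_kernel(ci - c0); wc <- wc / sum(wc)
    as.numeric(wr %*% mat[r0, c0, drop = FALSE] %*% wc)
  }, 0)
}

#' Localize microbubbles across a frame stack
#'
#' Full per-block localization pipeline: SVD clutter filtering, Lanczos
#' spatial interpolation, Gaussian-template correlation, local-maxima
#' detection with a correlation threshold, subpixel quadratic refinement,
#' and backscatter registration. Positions are returned in micrometres and
#' on the fine output grid.
#'
#' @details
#' Because the correlation is normalized, it is blind to amplitude: smooth
#' low-amplitude noise can correlate well with the template. Detections are
#' therefore additionally gated on their amplitude exceeding
#' `min_amplitude_snr` times the robust (median absolute deviation) noise
#' level of the filtered block — the practical reading of keeping only the
#' most intense correlation maxima. On noiseless scenes the gate vanishes.
#'
#' @param stack a [frame_stack()].
#' @param acq an [acquisition_config()].
#' @param psf_sigma_um Gaussian PSF sigma; default matches the
#'   renderer's PSF (FWHM of 1.5 wavelengths).
#' @param corr_threshold minimum correlation (default 0.7).
#' @param svd_cut singular values removed per block (default the ULM cut).
#' @param block_size frames per block.
#' After non-maximum suppression, residual sidelobes are rejected: the
#' clutter filter leaves ringing around each echo whose rectified
#' magnitude can correlate with the template, so a weaker peak within
#' `sidelobe_radius_fwhm` point-spread widths of a stronger one is kept
#' only if its amplitude exceeds `sidelobe_ratio` of the stronger peak
#' (two genuine bubbles of comparable brightness survive).
#'
#' @param min_amplitude_snr amplitude gate in robust noise sigmas.
#' @param min_amplitude_frac second amplitude gate as a fraction of the
#'   block's 95th-percentile detection amplitude: the clutter filter
#'   leaves a rectified residue along each bubble's path (its removed
#'   time-averaged ribbon) that re-detects as slowly drifting ghosts at
#'   20-40% of a genuine echo; genuine microbubble echoes are tightly
#'   distributed, so the relative gate removes ghosts at a ~2% cost.
#' @param sidelobe_radius_fwhm sidelobe rejection radius, PSF FWHMs.
#' @param sidelobe_ratio amplitude ratio below which a nearby weaker peak
#'   is treated as a sidelobe.
#' @return Tibble of detections: `frame` (0-based), `t_s`, `x_um`, `z_um`,
#'   `corr`, `backscatter`, `fine_col`, `fine_row` (0-based fine-grid
#'   pixel), `flagged`.
#' @export
localize_stack <- function(stack, acq = acquisition_config(),
                           psf_sigma_um = NULL, corr_threshold = 0.7,
                           svd_cut = acq$svd_cut_ulm,
                           block_size = acq$block_size,
                           min_amplitude_snr = 4,
                           min_amplitude_frac = 0.4,
                           sidelobe_radius_fwhm = 2.5,
                           sidelobe_ratio = 0.4) {
  grid <- stack$grid
  f <- grid$interp_factor
  if (is.null(psf_sigma_um))
    psf_sigma_um <- default_psf_sigma_um(acq)
  sig_px <- c(psf_sigma_um / (grid$native_pitch_z / f),
              psf_sigma_um / (grid$native_pitch_x / f))
  hz <- ceiling(3 * sig_px[1]); hx <- ceiling(3 * sig_px[2])
  gz <- exp(-(-hz:hz)^2 / (2 * sig_px[1]^2))
  gx <- exp(-(-hx:hx)^2 / (2 * sig_px[2]^2))
  hw <- max(hz, hx)
  fwhm <- 2.3548 * mean(sig_px)
  Wz <- lanczos_matrix(grid$n_z_native, f)
  Wx <- lanczos_matrix(grid$n_x_native, f)
  fp <- fine_pitch(grid)
  blocks <- iter_blocks(stack, block_size)
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    blk <- svd_filter(blocks[[bi]], svd_cut)
    bs <- dim(blk$values)[3]
    interp <- array(0, c(nrow(Wz), nrow(Wx), bs))
    for (k in seq_len(bs))
      interp[, , k] <- Wz %*% abs(blk$values[, , k]) %*% t(Wx)
    sig_noise <- stats::mad(interp[seq(1, length(interp),
                                       length.out = min(2e5,
                                                        length(interp)))])
    pks <- cpp_zncc_peaks(interp, gz, gx, corr_threshold, hw,
                          min_amplitude_snr * sig_noise)
    if (length(pks$frame) == 0) next
    pk <- tibble(row = pks$row, col = pks$col, k = pks$frame,
                 corr = pks$corr, amp = pks$amp)
    if (min_amplitude_frac > 0 && nrow(pk) > 0) {
      amp_ref <- quantile(pk$amp, 0.95, names = FALSE)
      pk <- pk[pk$amp >= min_amplitude_frac * amp_ref, , drop = FALSE]
    }
    if (nrow(pk) == 0) next
    pks$neigh <- pks$neigh[pks$amp >= if (min_amplitude_frac > 0)
      min_amplitude_frac * amp_ref else -Inf, , drop = FALSE]
    rf <- refine_from_neigh(pks$neigh)
    pk$drow <- rf$drow; pk$dcol <- rf$dcol; pk$flagged <- rf$flagged
    keep <- unlist(lapply(split(seq_len(nrow(pk)), pk$k), function(i) {
      i1 <- i[nms_keep(pk$row[i1 <- i], pk$col[i], pk$corr[i], fwhm)]
      i1[sidelobe_keep(pk$row[i1], pk$col[i1], pk$amp[i1],
                       sidelobe_radius_fwhm * fwhm, sidelobe_ratio)]
    }), use.names = FALSE)
    pk <- pk[keep, , drop = FALSE]
    bsc <- numeric(nrow(pk))
    for (kk in unique(pk$k)) {
      sel <- pk$k == kk
      bsc[sel] <- bilinear_at(interp[, , kk], pk$row[sel] + pk$drow[sel],
                              pk$col[sel] + pk$dcol[sel])
    }
    x_um <- ((pk$col - 1 + pk$dcol) / f + 0.5) * grid$native_pitch_x
    z_um <- ((pk$row - 1 + pk$drow) / f + 0.5) * grid$native_pitch_z
    frame0 <- blk$start_frame + pk$k - 1L
    out[[bi]] <- tibble(frame = as.integer(frame0),
                        t_s = frame0 / stack$frame_rate_hz,
                        x_um = x_um, z_um = z_um, corr = pk$corr,
                        backscatter = bsc,
                        fine_col = as.integer(floor(x_um / fp["x"])),
                        fine_row = as.integer(floor(z_um / fp["z"])),
                        flagged = pk$flagged)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble(frame = integer(), t_s = numeric(), x_um = numeric(),
                  z_um = numeric(), corr = numeric(), backscatter = numeric(),
                  fine_col = integer(), fine_row = integer(),
                  flagged = logical())
  arrange(res, .data$frame, .data$x_um)
}
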