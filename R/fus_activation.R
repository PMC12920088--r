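#' Power Doppler series
#'
#' One image per complete block of `block_size` compound frames: the block
#' is SVD clutter-filtered (60 singular values removed by default, to
#' discard tissue motion) and each pixel holds the mean squared magnitude
#' over the block, proportional to cerebral blood volume. At 500 Hz and
#' 200-frame blocks the block rate is 2.5 Hz.
#'
#' @param stack a [frame_stack()] on the native (Doppler) grid.
#' @param acq an [acquisition_config()].
#' @param svd_cut singular values removed (default `acq$svd_cut_fus`).
#' @param block_size frames per block.
#' @return A `power_doppler_series`: array `values (nz, nx, n_blocks)`,
#'   block times `t_s` (block centers), `block_rate_hz`, `grid`.
#' @export
power_doppler <- function(stack, acq = acquisition_config(),
                          svd_cut = acq$svd_cut_fus,
                          block_size = acq$block_size) {
  blocks <- iter_blocks(stack, block_size)
  nz <- dim(stack$values)[1]; nx <- dim(stack$values)[2]
  pd <- array(0, c(nz, nx, length(blocks)))
  for (b in seq_along(blocks)) {
    fb <- svd_filter(blocks[[b]], svd_cut)
    pd[, , b] <- apply(abs(fb$values)^2, c(1, 2), mean)
  }
  t_s <- (vapply(blocks, function(b) b$start_frame, 0) + block_size / 2) /
    stack$frame_rate_hz
  structure(list(values = pd, t_s = t_s,
                 block_rate_hz = stack$frame_rate_hz / block_size,
                 grid = stack$grid),
            class = "power_doppler_series")
}

#' @export
print.power_doppler_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<power_doppler_series> %d x %d px, %d blocks @ %g Hz\n",
              d[1], d[2], d[3], x$block_rate_hz))
  invisible(x)
}

#' Single-gamma haemodynamic response function
#'
#' Canonical rodent HRF kernel: a gamma density with configurable peak time
#' (default 1.5 s) and unit area.
#'
#' @param t_s times, s.
#' @param peak_s time to peak.
#' @param shape gamma shape parameter.
#' @return HRF values.
#' @export
hrf_gamma <- function(t_s, peak_s = 1.5, shape = 3) {
  scale <- peak_s / (shape - 1)
  dgamma(t_s, shape = shape, scale = scale)
}

# stimulus boxcar convolved with the HRF, sampled at arbitrary times
hrf_regressor <- function(t_out, protocol, peak_s = 1.5, shape = 3,
                          dt = 0.1) {
  total <- max(t_out) + dt
  tt <- seq(0, total, by = dt)
  P <- pattern_duration(protocol)
  tp <- tt %% P
  box <- as.numeric(tp >= protocol$rest_s &
                      tp < protocol$rest_s + protocol$stim_s)
  h <- hrf_gamma(seq(0, 8 * peak_s, by = dt), peak_s, shape)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tt)] * dt
  approx(tt, conv, t_out, rule = 2)$y
}

#' GLM activation map from a power Doppler series
#'
#' Per pixel: linear detrending, then ordinary least squares of the power
#' Doppler series on the stimulus boxcar convolved with a canonical
#' haemodynamic response function (plus intercept); the regression t
#' statistic is mapped to a z score. Constant pixels return z = 0.
#'
#' @param pd a [power_doppler()] result covering at least one full pattern.
#' @param protocol a [stimulus_protocol()].
#' @param hrf_peak_s,hrf_shape HRF parameters (see [hrf_gamma()]).
#' @return A `fus_zmap`: `z` matrix, the regressor, block times, residual
#'   degrees of freedom and grid.
#' @export
glm_activation <- function(pd, protocol, hrf_peak_s = 1.5, hrf_shape = 3) {
  nb <- dim(pd$values)[3]
  if (max(pd$t_s) < pattern_duration(protocol) - 1 / pd$block_rate_hz)
    abort("power Doppler series must cover at least one full pattern")
  reg <- hrf_regressor(pd$t_s, protocol, hrf_peak_s, hrf_shape)
  Y <- matrix(pd$values, ncol = nb)         # pixels x blocks
  tt <- pd$t_s
  # linear detrending (keep the mean)
  Xd <- cbind(1, tt - mean(tt))
  coefd <- solve(crossprod(Xd), t(Xd) %*% t(Y))
  Yd <- t(Y) - Xd[, 2, drop = FALSE] %*% coefd[2, , drop = FALSE]
  X <- cbind(1, reg)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% t(X) %*% Yd
  res <- Yd - X %*% B
  df <- nb - 2L
  s2 <- colSums(res^2) / df
  # constant (zero-variance) pixel series carry no information: z = 0
  ybar2 <- colMeans(Yd^2)
  degenerate <- s2 <= 1e-12 * pmax(ybar2, 1e-300)
  se <- sqrt(pmax(s2 * XtXi[2, 2], 0))
  tval <- ifelse(se > 0 & !degenerate, B[2, ] / se, 0)
  z <- sign(tval) * qnorm(pt(abs(tval), df, lower.tail = FALSE,
                             log.p = TRUE),
                          lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(z)] <- 0
  structure(list(z = matrix(z, dim(pd$values)[1], dim(pd$values)[2]),
                 regressor = reg, t_s = pd$t_s, df = df, grid = pd$grid),
            class = "fus_zmap")
}

#' @export
print.fus_zmap <- function(x, ...) {
  cat(sprintf("<fus_zmap> %d x %d px, peak z = %.2f\n",
              nrow(x$z), ncol(x$z), max(x$z)))
  invisible(x)
}

#' 20-90% rise time of a response curve
#'
#' Time taken to climb from 20% to 90% of the curve's peak, with linear
#' interpolation between samples (a linear ramp of duration `d` therefore
#' gives exactly `0.7 * d`).
#'
#' @param t_s sample times.
#' @param y response values (baseline-relative).
#' @return Rise time, s (`NA` if the curve never reaches the thresholds).
#' @export
rise_time <- function(t_s, y) {
  pk <- max(y)
  if (pk <= 0) return(NA_real_)
  cross <- function(level) {
    i <- which(y >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(t_s[1])
    t_s[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) *
      (t_s[i] - t_s[i - 1])
  }
  t20 <- cross(0.2 * pk); t90 <- cross(0.9 * pk)
  t90 - t20
}

#' ROI cerebral blood volume response
#'
#' Places a circular region of interest (1.4 mm diameter by default) on the
#' peak z score, averages the power Doppler series over the ROI, normalizes
#' each pattern to its own pre-stimulation baseline, and pattern-averages
#' the resulting per-cent change in cerebral blood volume. Early and late
#' amplitudes are means over protocol-relative windows (36-44 s and
#' 44-60 s for the default 30/30 protocol); the rise time is the 20-90%
#' climb of the pattern-averaged curve.
#'
#' @param pd a [power_doppler()] result.
#' @param z_map a [glm_activation()] result.
#' @param protocol a [stimulus_protocol()].
#' @param roi_diameter_mm ROI diameter.
#' @param early_window_s,late_window_s pattern-relative windows, s.
#' @return A `cbv_response`: `$curve` tibble (`t_pattern_s`, `dcbv_pct`),
#'   `$baseline_cbv`, `$early_pct`, `$late_pct`, `$rise_time_s`, `$roi`.
#' @export
roi_response <- function(pd, z_map, protocol, roi_diameter_mm = 1.4,
                         early_window_s = c(36, 44),
                         late_window_s = c(44, 60)) {
  if (!all(is.finite(z_map$z))) abort("z map contains non-finite values")
  g <- pd$grid
  pk <- which(z_map$z == max(z_map$z), arr.ind = TRUE)[1, ]
  cz <- (pk[1] - 0.5) * g$native_pitch_z
  cx <- (pk[2] - 0.5) * g$native_pitch_x
  r_um <- roi_diameter_mm * 1000 / 2
  zc <- (seq_len(g$n_z_native) - 0.5) * g$native_pitch_z
  xc <- (seq_len(g$n_x_native) - 0.5) * g$native_pitch_x
  roi <- outer(zc, xc, function(z, x) (z - cz)^2 + (x - cx)^2 <= r_um^2)
  n_ideal <- pi * r_um^2 / (g$native_pitch_z * g$native_pitch_x)
  if (sum(roi) < 0.5 * n_ideal)
    abort("ROI clips more than 50% outside the field of view")
  nb <- dim(pd$values)[3]
  y <- vapply(seq_len(nb), function(b) mean(pd$values[, , b][roi]), 0)
  P <- pattern_duration(protocol)
  pat <- floor(pd$t_s / P + 1e-12)
  tp <- pd$t_s - pat * P
  base_by_pat <- tapply(y[tp < protocol$rest_s], pat[tp < protocol$rest_s],
                        mean)
  baseline_cbv <- mean(base_by_pat)
  if (baseline_cbv <= 0) abort("baseline CBV must be positive")
  dcbv <- 100 * (y - base_by_pat[as.character(pat)]) /
    base_by_pat[as.character(pat)]
  curve <- tibble(tp = tp, dcbv = dcbv) |>
    group_by(.data$tp) |>
    summarise(dcbv_pct = mean(.data$dcbv), .groups = "drop") |>
    dplyr::rename(t_pattern_s = "tp")
  win_mean <- function(w) {
    sel <- curve$t_pattern_s >= w[1] & curve$t_pattern_s < w[2]
    if (!any(sel)) NA_real_ else mean(curve$dcbv_pct[sel])
  }
  structure(list(curve = curve, baseline_cbv = baseline_cbv,
                 early_pct = win_mean(early_window_s),
                 late_pct = win_mean(late_window_s),
                 rise_time_s = rise_time(curve$t_pattern_s, curve$dcbv_pct),
                 roi = list(center_um = c(x = cx, z = cz), radius_um = r_um,
                            n_px = sum(roi)),
                 n_patterns = length(base_by_pat)),
            class = "cbv_response")
}

#' @export
print.cbv_response <- function(x, ...) {
  cat(sprintf(
    "<cbv_response> early %.2f%%, late %.2f%%, rise %.2f s (baseline %.3g)\n",
    x$early_pct, x$late_pct, x$rise_time_s, x$baseline_cbv))
  invisible(x)
}

#' @export
tidy.cbv_response <- function(x, ...) x$curve

#' @export
glance.cbv_response <- function(x, ...) {
  tibble(baseline_cbv = x$baseline_cbv, early_pct = x$early_pct,
         late_pct = x$late_pct, rise_time_s = x$rise_time_s,
         peak_pct = max(x$curve$dcbv_pct), n_patterns = x$n_patterns)
}
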