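#' Microscopic activation map
#'
#' Relative microbubble-flow increase per fine pixel,
#' `(stimulation - baseline) / baseline`, defined only where the baseline
#' flow is positive; other pixels are masked (NA), never infinite.
#'
#' @param baseline,stimulation [accumulate_maps()] results on the same grid
#'   (e.g. from [split_baseline_stim()]).
#' @return An `activation_map`: `values` matrix (NA outside the mask),
#'   `mask`, and the two source maps.
#' @export
activation_map <- function(baseline, stimulation) {
  if (!identical(dim(baseline$mb_flow), dim(stimulation$mb_flow)) ||
      !identical(unclass(baseline$grid), unclass(stimulation$grid)))
    abort("baseline and stimulation maps must share the same grid")
  mask <- baseline$mb_flow > 0
  values <- matrix(NA_real_, nrow(mask), ncol(mask))
  values[mask] <- (stimulation$mb_flow[mask] - baseline$mb_flow[mask]) /
    baseline$mb_flow[mask]
  structure(list(values = values, mask = mask, baseline = baseline,
                 stimulation = stimulation, grid = baseline$grid),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d defined px, median increase %.1f%%\n",
              sum(x$mask), 100 * median(x$values[x$mask])))
  invisible(x)
}

#' @export
tidy.activation_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  fp <- fine_pitch(x$grid)
  tibble(fine_row = idx[, 1] - 1L, fine_col = idx[, 2] - 1L,
         x_um = (idx[, 2] - 0.5) * fp[["x"]],
         z_um = (idx[, 1] - 0.5) * fp[["z"]],
         relative_increase = x$values[x$mask])
}

#' @export
glance.activation_map <- function(x, ...) {
  v <- x$values[x$mask]
  tibble(n_defined_px = length(v), median_increase = median(v),
         mean_increase = mean(v))
}

#' Aggregate flow increase over a region
#'
#' Ratio of ROI-aggregated stimulation to baseline flow, minus one. More
#' robust than averaging per-pixel ratios when single-pixel counts are low.
#'
#' @param amap an [activation_map()].
#' @param mask logical matrix on the fine grid (`NULL` = all defined px).
#' @return Fractional flow increase.
#' @export
activation_increase <- function(amap, mask = NULL) {
  if (is.null(mask)) mask <- amap$mask
  b <- sum(amap$baseline$mb_flow[mask])
  s <- sum(amap$stimulation$mb_flow[mask])
  if (b <= 0) abort("no baseline flow in the region")
  s / b - 1
}

band_rows <- function(grid, depth_range_um) {
  fp <- fine_pitch(grid)
  zc <- (seq_len(fine_dim(grid)[["n_row"]]) - 0.5) * fp[["z"]]
  zc >= depth_range_um[1] & zc < depth_range_um[2]
}

#' Depth-resolved activation signal
#'
#' Spatial mean of the microbubble flow over a vessel mask intersected with
#' a depth band (the arteriole-capillary transition zone lies below
#' `depth_split_um`), per within-pattern time step of a pattern-averaged
#' stack, normalized so the baseline window mean is 100%. Early and late
#' increases are means over the stated pattern-relative windows.
#'
#' @param pstack a [pattern_average()] result.
#' @param vessel_mask logical matrix on the fine grid (e.g. union of
#'   segmented arteriole masks).
#' @param depth_split_um boundary between the upper and deep bands.
#' @param early_window_s,late_window_s pattern-relative windows, s.
#' @return An `activation_signal` tibble: `band`, `window_in_pattern`,
#'   `t_pattern_s`, `mb_flow`, `signal_pct`; per-band early/late increases
#'   in `attr(, "metrics")`.
#' @export
activation_signal <- function(pstack, vessel_mask, depth_split_um = 400,
                              early_window_s = c(30, 40),
                              late_window_s = c(40, 60)) {
  grid <- pstack$grid
  fd <- fine_dim(grid)
  bottom <- fd[["n_row"]] * fine_pitch(grid)[["z"]]
  bands <- list(upper = c(0, depth_split_um),
                deep = c(depth_split_um, bottom))
  marks <- pstack$marks
  fp <- fine_pitch(grid)
  out <- list(); metrics <- list()
  for (bn in names(bands)) {
    rows_in <- band_rows(grid, bands[[bn]])
    bmask <- vessel_mask & matrix(rows_in, fd[["n_row"]], fd[["n_col"]])
    if (!any(bmask))
      abort(sprintf("vessel mask is empty in the %s band (%g-%g um)",
                    bn, bands[[bn]][1], bands[[bn]][2]))
    inside <- bmask[cbind(marks$fine_row + 1L, marks$fine_col + 1L)]
    mm <- marks[inside, , drop = FALSE]
    counts <- tabulate(mm$window_in_pattern + 1L, nbins = pstack$nt_prime)
    flow <- counts / (pstack$window_s * pstack$n_kept * sum(bmask))
    tmid <- (seq_len(pstack$nt_prime) - 0.5) * pstack$window_s
    base_sel <- tmid < pstack$protocol$rest_s
    base <- mean(flow[base_sel])
    if (base <= 0)
      abort(sprintf("no baseline flow in the %s band", bn))
    pct <- 100 * flow / base
    out[[bn]] <- tibble(band = bn,
                        window_in_pattern = seq_len(pstack$nt_prime) - 1L,
                        t_pattern_s = tmid, mb_flow = flow,
                        signal_pct = pct)
    wmean <- function(w) mean(pct[tmid >= w[1] & tmid < w[2]]) - 100
    metrics[[bn]] <- tibble(band = bn,
                            early_increase_pct = wmean(early_window_s),
                            late_increase_pct = wmean(late_window_s))
  }
  res <- bind_rows(out)
  attr(res, "metrics") <- bind_rows(metrics)
  class(res) <- c("activation_signal", class(res))
  res
}

#' @export
glance.activation_signal <- function(x, ...) attr(x, "metrics")

#' Per-pattern window signals
#'
#' Microbubble count per dynamic window and pattern inside a mask (whole
#' image if `NULL`); the input to [pattern_qc()].
#'
#' @param stack a [dynamic_stack()] result.
#' @param mask optional logical matrix on the fine grid.
#' @return Matrix `n_patterns x windows_per_pattern` of mark counts.
#' @export
window_signals <- function(stack, mask = NULL) {
  marks <- stack$marks
  if (!is.null(mask)) {
    inside <- mask[cbind(marks$fine_row + 1L, marks$fine_col + 1L)]
    marks <- marks[inside, , drop = FALSE]
  }
  np <- stack$protocol$n_patterns
  nwp <- stack$windows_per_pattern
  m <- matrix(0, np, nwp)
  if (nrow(marks)) {
    tb <- table(factor(marks$pattern, levels = 0:(np - 1)),
                factor(marks$window_in_pattern, levels = 0:(nwp - 1)))
    m <- matrix(as.numeric(tb), np, nwp)
  }
  m
}

#' Pattern and acquisition quality control
#'
#' Applies the pattern-selection rules: a pattern is kept only if the
#' Pearson correlation of its arteriolar microbubble-count signal with the
#' binary stimulus pattern exceeds `corr_threshold` (0.3), the correlation
#' of the contralateral (non-stimulated) signal lies within
#' `[-contra_band, contra_band]` (0.5), and — automating the manual
#' stable-injection screen — the coefficient of variation of the global
#' microbubble count across the pattern stays below `stability_cv`.
#' The acquisition is kept only if the pattern-averaged signal of the kept
#' patterns reaches a `min_increase_pct` (10%) mean increase during
#' stimulation. Zero-variance signals yield undefined correlations and are
#' rejected with a reason.
#'
#' @param roi_signals matrix `n_patterns x n_windows` of ROI microbubble
#'   counts (see [window_signals()]).
#' @param protocol a [stimulus_protocol()].
#' @param contra_signals matrix like `roi_signals` for the contralateral
#'   region (`NULL` skips the rule).
#' @param global_signals matrix of whole-image counts (`NULL` skips the
#'   stability screen).
#' @param window_s dynamic window, s.
#' @param corr_threshold,contra_band,stability_cv,min_increase_pct
#'   thresholds.
#' @return A `pattern_qc_report`: `$patterns` tibble (per-pattern
#'   correlations, CV, kept flag, reason), `$mean_increase_pct`,
#'   `$acquisition_kept`, `$thresholds`.
#' @export
pattern_qc <- function(roi_signals, protocol, contra_signals = NULL,
                       global_signals = NULL, window_s = 2,
                       corr_threshold = 0.3, contra_band = 0.5,
                       stability_cv = 0.3, min_increase_pct = 10) {
  np <- nrow(roi_signals); nw <- ncol(roi_signals)
  tmid <- (seq_len(nw) - 0.5) * window_s
  box <- as.numeric(tmid >= protocol$rest_s &
                      tmid < protocol$rest_s + protocol$stim_s)
  safe_cor <- function(v) {
    if (sd(v) == 0 || sd(box) == 0) return(NA_real_)
    cor(v, box)
  }
  stim_corr <- apply(roi_signals, 1, safe_cor)
  contra_corr <- if (is.null(contra_signals)) rep(NA_real_, np) else
    apply(contra_signals, 1, safe_cor)
  global_cv <- if (is.null(global_signals)) rep(NA_real_, np) else
    apply(global_signals, 1, function(v)
      if (mean(v) > 0) sd(v) / mean(v) else Inf)
  kept <- rep(TRUE, np); reason <- rep(NA_character_, np)
  for (p in seq_len(np)) {
    if (is.na(stim_corr[p])) {
      kept[p] <- FALSE; reason[p] <- "zero-variance ROI signal"
    } else if (stim_corr[p] <= corr_threshold) {
      kept[p] <- FALSE; reason[p] <- "stimulus correlation below threshold"
    } else if (!is.na(contra_corr[p]) && abs(contra_corr[p]) > contra_band) {
      kept[p] <- FALSE; reason[p] <- "contralateral correlation out of band"
    } else if (!is.na(global_cv[p]) && global_cv[p] >= stability_cv) {
      kept[p] <- FALSE; reason[p] <- "unstable global microbubble flow"
    }
  }
  mean_increase <- NA_real_
  acquisition_kept <- FALSE
  if (any(kept)) {
    avg <- colMeans(roi_signals[kept, , drop = FALSE])
    base <- mean(avg[tmid < protocol$rest_s])
    if (base > 0) {
      mean_increase <- 100 * (mean(avg[box == 1]) / base - 1)
      acquisition_kept <- mean_increase >= min_increase_pct
    }
  }
  structure(list(
    patterns = tibble(pattern = seq_len(np) - 1L, stim_corr = stim_corr,
                      contra_corr = contra_corr, global_cv = global_cv,
                      kept = kept, reason = reason),
    mean_increase_pct = mean_increase,
    acquisition_kept = acquisition_kept,
    thresholds = list(corr_threshold = corr_threshold,
                      contra_band = contra_band,
                      stability_cv = stability_cv,
                      min_increase_pct = min_increase_pct)),
    class = "pattern_qc_report")
}

#' @export
print.pattern_qc_report <- function(x, ...) {
  cat(sprintf(
    "<pattern_qc_report> %d/%d patterns kept; mean increase %.1f%%; acquisition %s\n",
    sum(x$patterns$kept), nrow(x$patterns), x$mean_increase_pct,
    if (x$acquisition_kept) "kept" else "rejected"))
  invisible(x)
}

#' @export
tidy.pattern_qc_report <- function(x, ...) x$patterns

#' @export
glance.pattern_qc_report <- function(x, ...) {
  tibble(n_patterns = nrow(x$patterns), n_kept = sum(x$patterns$kept),
         mean_increase_pct = x$mean_increase_pct,
         acquisition_kept = x$acquisition_kept)
}

#' Group tracks into raw-track display windows
#'
#' Assigns each track to the time window containing its first detection
#' (4-s windows by default), for overlaying raw microbubble tracks on
#' cumulative activation maps.
#'
#' @param tracks a `track_set`.
#' @param window_s window length.
#' @param t0 start of the first window, s.
#' @return Tibble: `track_id`, `window` (0-based), `window_start_s`.
#' @export
track_windows <- function(tracks, window_s = 4, t0 = 0) {
  if (window_s <= 0) abort("window_s must be positive")
  det <- tracks$detections
  if (nrow(det) == 0)
    return(tibble(track_id = integer(), window = integer(),
                  window_start_s = numeric()))
  first <- det |> group_by(.data$track_id) |>
    summarise(t_first = min(.data$frame) / tracks$frame_rate,
              .groups = "drop")
  w <- as.integer(floor((first$t_first - t0) / window_s))
  tibble(track_id = first$track_id, window = w,
         window_start_s = t0 + w * window_s)
}
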