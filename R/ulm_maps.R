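marks_or_tracks <- function(x, grid) {
  if (inherits(x, "track_set")) ulm_marks(x, grid) else as_tibble(x)
}

#' Accumulate presence marks into super-resolved maps
#'
#' Per fine-grid pixel over the accumulation window: microbubble flow
#' (marks per second, MBs px^-1 s^-1), mean velocity components, mean scalar
#' speed and mean backscatter amplitude. Pixels without marks hold exactly 0.
#'
#' @param tracks a `track_set` or a mark table ([rasterize_steps()]).
#' @param grid a [grid_spec()].
#' @param window `(start, end)` seconds; `NULL` uses `[0, max(t) + dt)` of
#'   the marks with `duration = end - start` for the flow normalization.
#' @return An `ulm_maps` object: matrices `mb_flow`, `vx`, `vz`, `speed`,
#'   `backscatter` plus the window and grid.
#' @export
accumulate_maps <- function(tracks, grid, window = NULL) {
  marks <- marks_or_tracks(tracks, grid)
  if (is.null(window)) {
    window <- c(0, if (nrow(marks)) max(marks$t_s) + 1e-9 else 1)
  }
  if (diff(window) <= 0) abort("window duration must be positive")
  marks <- filter(marks, .data$t_s >= window[1], .data$t_s < window[2])
  build_maps(marks, grid, duration = diff(window), window = window)
}

build_maps <- function(marks, grid, duration, window,
                       n_accumulations = 1) {
  fd <- fine_dim(grid)
  nzf <- fd[["n_row"]]; nxf <- fd[["n_col"]]
  zero <- matrix(0, nzf, nxf)
  maps <- list(mb_flow = zero, vx = zero, vz = zero, speed = zero,
               backscatter = zero)
  if (nrow(marks)) {
    idx <- marks$fine_row + 1L + marks$fine_col * nzf
    counts <- tabulate(idx, nbins = nzf * nxf)
    stopifnot(all(idx >= 1), all(idx <= nzf * nxf))
    gsum <- function(v) {
      out <- numeric(nzf * nxf)
      s <- rowsum(v, idx)
      out[as.integer(rownames(s))] <- s
      out
    }
    occ <- counts > 0
    mean_of <- function(v) {
      out <- gsum(v)
      out[occ] <- out[occ] / counts[occ]
      matrix(out, nzf, nxf)
    }
    # velocity components: weight marks by 1/step_px to undo the
    # length-biased sampling of long steps (see rasterize_steps)
    w <- if ("step_px" %in% names(marks)) 1 / marks$step_px
         else rep(1, nrow(marks))
    wsum <- gsum(w)
    wmean_of <- function(v) {
      out <- gsum(w * v)
      out[occ] <- out[occ] / wsum[occ]
      matrix(out, nzf, nxf)
    }
    maps$mb_flow <- matrix(counts / (duration * n_accumulations), nzf, nxf)
    maps$speed <- mean_of(marks$speed_mm_s)
    maps$vx <- wmean_of(marks$vx_mm_s)
    maps$vz <- wmean_of(marks$vz_mm_s)
    bs <- marks$backscatter
    bs[is.na(bs)] <- 0
    maps$backscatter <- mean_of(bs)
  }
  structure(c(maps, list(window = window, grid = grid,
                         n_marks = nrow(marks))),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("<ulm_maps> %d x %d fine px, window [%g, %g) s, %d marks\n",
              nrow(x$mb_flow), ncol(x$mb_flow), x$window[1], x$window[2],
              x$n_marks))
  invisible(x)
}

#' @export
tidy.ulm_maps <- function(x, ...) {
  fp <- fine_pitch(x$grid)
  d <- dim(x$mb_flow)
  tibble(fine_row = rep(seq_len(d[1]) - 1L, d[2]),
         fine_col = rep(seq_len(d[2]) - 1L, each = d[1]),
         x_um = (rep(seq_len(d[2]) - 1L, each = d[1]) + 0.5) * fp[["x"]],
         z_um = (rep(seq_len(d[1]) - 1L, d[2]) + 0.5) * fp[["z"]],
         mb_flow = as.vector(x$mb_flow), speed = as.vector(x$speed),
         vx = as.vector(x$vx), vz = as.vector(x$vz),
         backscatter = as.vector(x$backscatter))
}

#' @export
glance.ulm_maps <- function(x, ...) {
  occ <- x$mb_flow > 0
  tibble(n_occupied_px = sum(occ),
         total_flow = sum(x$mb_flow),
         mean_speed_mm_s = if (any(occ)) mean(x$speed[occ]) else 0,
         window_s = diff(x$window))
}

#' Dynamic (time-resolved) ULM stack
#'
#' Splits the acquisition into consecutive non-overlapping accumulation
#' windows (2 s by default, i.e. 5 blocks of 200 frames) and indexes every
#' presence mark by window, pattern and within-pattern window. Per-window
#' maps are materialized on demand with [window_map()] to keep memory
#' proportional to the marks, not to `Nt` full frames of the fine grid.
#'
#' @param tracks a `track_set` or mark table.
#' @param grid a [grid_spec()].
#' @param protocol a [stimulus_protocol()].
#' @param window_s accumulation window, s (must divide the pattern duration).
#' @param duration_s total duration; defaults to the full protocol.
#' @return A `dynamic_ulm_stack` (marks, `n_windows`, `windows_per_pattern`).
#' @export
dynamic_stack <- function(tracks, grid, protocol, window_s = 2,
                          duration_s = NULL) {
  P <- pattern_duration(protocol)
  nwp <- P / window_s
  if (abs(nwp - round(nwp)) > 1e-9)
    abort("window_s must divide the pattern duration")
  if (is.null(duration_s)) duration_s <- protocol_duration(protocol)
  nw <- duration_s / window_s
  if (abs(nw - round(nw)) > 1e-9)
    abort("duration must be a whole number of windows")
  marks <- marks_or_tracks(tracks, grid)
  marks <- filter(marks, .data$t_s < duration_s)
  marks$window <- as.integer(floor(marks$t_s / window_s + 1e-12))
  marks$pattern <- as.integer(floor(marks$t_s / P + 1e-12))
  marks$window_in_pattern <- marks$window - marks$pattern * as.integer(round(nwp))
  structure(list(marks = marks, n_windows = as.integer(round(nw)),
                 windows_per_pattern = as.integer(round(nwp)),
                 window_s = window_s, duration_s = duration_s,
                 grid = grid, protocol = protocol),
            class = "dynamic_ulm_stack")
}

#' @export
print.dynamic_ulm_stack <- function(x, ...) {
  cat(sprintf("<dynamic_ulm_stack> %d windows of %g s (%d per pattern), %d marks\n",
              x$n_windows, x$window_s, x$windows_per_pattern, nrow(x$marks)))
  invisible(x)
}

#' Materialize one window of a dynamic stack
#' @param stack a `dynamic_ulm_stack` or `pattern_averaged_stack`.
#' @param index 0-based window index (within-pattern index for the
#'   pattern-averaged stack).
#' @return An [accumulate_maps()] result.
#' @export
window_map <- function(stack, index) {
  if (inherits(stack, "pattern_averaged_stack")) {
    marks <- filter(stack$marks, .data$window_in_pattern == index)
    return(build_maps(marks, stack$grid, duration = stack$window_s,
                      window = c(index, index + 1) * stack$window_s,
                      n_accumulations = stack$n_kept))
  }
  marks <- filter(stack$marks, .data$window == index)
  build_maps(marks, stack$grid, duration = stack$window_s,
             window = c(index, index + 1) * stack$window_s)
}

#' Pattern-averaged ULM stack
#'
#' Accumulates the marks of the kept stimulation patterns at the same
#' within-pattern time point, giving `Nt' = pattern_duration / window`
#' maps (35 with the defaults); counts are summed over kept patterns and
#' flows normalized by the number of kept patterns, so with identical
#' patterns the average equals any single pattern.
#'
#' @param stack a [dynamic_stack()] result.
#' @param kept_patterns 0-based pattern indices to keep; `NULL` keeps all.
#' @return A `pattern_averaged_stack`.
#' @export
pattern_average <- function(stack, kept_patterns = NULL) {
  if (is.null(kept_patterns))
    kept_patterns <- seq_len(stack$protocol$n_patterns) - 1L
  if (length(kept_patterns) == 0) abort("kept_patterns must be non-empty")
  marks <- filter(stack$marks, .data$pattern %in% kept_patterns)
  structure(list(marks = marks, nt_prime = stack$windows_per_pattern,
                 window_s = stack$window_s, n_kept = length(kept_patterns),
                 kept_patterns = as.integer(kept_patterns),
                 grid = stack$grid, protocol = stack$protocol),
            class = "pattern_averaged_stack")
}

#' @export
print.pattern_averaged_stack <- function(x, ...) {
  cat(sprintf("<pattern_averaged_stack> Nt' = %d windows of %g s over %d kept patterns\n",
              x$nt_prime, x$window_s, x$n_kept))
  invisible(x)
}

#' Baseline and stimulation map subsets
#'
#' Splits marks by pattern-relative time into the baseline window
#' `[0, rest)` and the stimulation window `[rest, rest + stim)`; the
#' post-stimulation interval belongs to neither. Each map is normalized by
#' its own total accumulated duration, so baseline and stimulation flows
#' are directly comparable rates.
#'
#' @param tracks a `track_set` or mark table.
#' @param grid a [grid_spec()].
#' @param protocol a [stimulus_protocol()].
#' @param n_patterns number of patterns actually covered by the data;
#'   defaults to the protocol's.
#' @return A list with `baseline` and `stimulation` [accumulate_maps()]
#'   results.
#' @export
split_baseline_stim <- function(tracks, grid, protocol, n_patterns = NULL) {
  marks <- marks_or_tracks(tracks, grid)
  if (is.null(n_patterns)) n_patterns <- protocol$n_patterns
  P <- pattern_duration(protocol)
  tp <- marks$t_s %% P
  base <- marks[tp < protocol$rest_s, , drop = FALSE]
  stim <- marks[tp >= protocol$rest_s &
                  tp < protocol$rest_s + protocol$stim_s, , drop = FALSE]
  list(baseline = build_maps(base, grid,
                             duration = protocol$rest_s * n_patterns,
                             window = c(0, protocol$rest_s)),
       stimulation = build_maps(stim, grid,
                                duration = protocol$stim_s * n_patterns,
                                window = c(protocol$rest_s,
                                           protocol$rest_s + protocol$stim_s)))
}

#' Display transform for flow maps
#'
#' Square root of the microbubble flow, for rendering only (compresses the
#' dynamic range so the smallest vessels stay visible); analysis always
#' uses the linear values.
#'
#' @param map an `ulm_maps` object or a non-negative matrix.
#' @return The square-root matrix.
#' @export
display_transform <- function(map) {
  m <- if (inherits(map, "ulm_maps")) map$mb_flow else map
  if (any(m < 0)) abort("display_transform expects non-negative values")
  sqrt(m)
}
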