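#' Link detections into microbubble tracks
#'
#' Frame-to-frame optimal bipartite assignment minimizing total displacement,
#' gated at `max_speed_mm_s / frame_rate` (200 um per frame at the default
#' 100 mm/s and 500 Hz). Unassigned detections start new tracks; a missed
#' frame terminates a track (no gap closing), and tracks with fewer than
#' `min_track_len` consecutive detections are discarded.
#'
#' Per-step velocities are derived from the linked trajectory after a light
#' positional smoothing (symmetric running mean of up to `smooth_window`
#' detections, shrinking near track ends): at 500 Hz an interframe
#' displacement of a few micrometres is comparable to the localization
#' noise, and differencing raw positions would bias scalar speeds upward;
#' the symmetric mean is exact for constant-velocity motion, so clean
#' kinematics are unaffected. Raw positions are kept in `$detections`.
#'
#' @param detections tibble with at least `frame`, `x_um`, `z_um` (extra
#'   columns such as `backscatter` and `corr` are carried along).
#' @param frame_rate compound frame rate, Hz.
#' @param max_speed_mm_s gating speed (default 100 mm/s).
#' @param min_track_len minimum detections per track (default 5).
#' @param smooth_window trajectory smoothing span, frames (1 disables).
#' @return A `track_set`: `$detections` (with `track_id`), `$steps`
#'   (per-step velocities), `$counts`, `$frame_rate`.
#' @export
link_tracks <- function(detections, frame_rate, max_speed_mm_s = 100,
                        min_track_len = 5L, smooth_window = 5L) {
  stopifnot(max_speed_mm_s > 0, frame_rate > 0)
  det <- arrange(as_tibble(detections), .data$frame)
  gate_um <- max_speed_mm_s * 1000 / frame_rate
  n <- nrow(det)
  track_id <- integer(n)
  if (n > 0) {
    BIG <- 1e12
    frames <- sort(unique(det$frame))
    idx_by_frame <- split(seq_len(n), det$frame)
    next_id <- 0L
    prev_idx <- integer(0)   # detection rows active in the previous frame
    prev_frame <- NA_integer_
    for (f in frames) {
      cur <- idx_by_frame[[as.character(f)]]
      if (!is.na(prev_frame) && f == prev_frame + 1L && length(prev_idx)) {
        m <- length(prev_idx); k <- length(cur)
        D <- sqrt(outer(det$x_um[prev_idx], det$x_um[cur], "-")^2 +
                  outer(det$z_um[prev_idx], det$z_um[cur], "-")^2)
        D[D > gate_um] <- BIG
        # birth/death construction: prev i may die via dummy column i,
        # detection j may be born via dummy row j; dummies pair at zero cost
        C <- matrix(BIG, m + k, k + m)
        C[seq_len(m), seq_len(k)] <- D
        C[cbind(seq_len(m), k + seq_len(m))] <- gate_um
        C[cbind(m + seq_len(k), seq_len(k))] <- gate_um
        C[m + seq_len(k), k + seq_len(m)] <- 0
        asg <- cpp_assignment(C)
        for (i in seq_len(m)) {
          j <- asg[i]
          if (j <= k && D[i, j] < BIG)
            track_id[cur[j]] <- track_id[prev_idx[i]]
        }
      }
      born <- cur[track_id[cur] == 0L]
      if (length(born)) {
        track_id[born] <- next_id + seq_along(born)
        next_id <- next_id + length(born)
      }
      prev_idx <- cur
      prev_frame <- f
    }
  }
  det$track_id <- track_id
  lens <- table(det$track_id)
  keep_ids <- as.integer(names(lens)[lens >= min_track_len])
  kept <- det[det$track_id %in% keep_ids, , drop = FALSE]
  # renumber by first appearance
  if (nrow(kept)) {
    first <- tapply(kept$frame, kept$track_id, min)
    ord <- as.integer(names(sort(first)))
    kept$track_id <- match(kept$track_id, ord)
    kept <- arrange(kept, .data$track_id, .data$frame)
  }
  smoothed <- kept
  if (smooth_window > 1 && nrow(kept)) {
    smoothed$x_um <- stats::ave(kept$x_um, kept$track_id,
                                FUN = function(v) runmean_sym(v, smooth_window))
    smoothed$z_um <- stats::ave(kept$z_um, kept$track_id,
                                FUN = function(v) runmean_sym(v, smooth_window))
  }
  steps <- track_steps(smoothed, frame_rate)
  structure(list(detections = kept, steps = steps,
                 counts = list(total = n, linked = nrow(kept),
                               discarded_short = n - nrow(kept)),
                 frame_rate = frame_rate,
                 max_speed_mm_s = max_speed_mm_s,
                 min_track_len = as.integer(min_track_len)),
            class = "track_set")
}

# symmetric running mean with window shrinking near the ends; exact for
# linear sequences
runmean_sym <- function(v, w) {
  n <- length(v)
  h <- pmin(w %/% 2L, seq_len(n) - 1L, n - seq_len(n))
  cs0 <- c(0, cumsum(v))
  lo <- seq_len(n) - h
  hi <- seq_len(n) + h
  (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d detections (%d discarded), %g Hz\n",
              length(unique(x$detections$track_id)), x$counts$linked,
              x$counts$discarded_short, x$frame_rate))
  invisible(x)
}

# per-step table for a detection tibble carrying track_id
track_steps <- function(det, frame_rate) {
  if (nrow(det) == 0)
    return(tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                  x0_um = numeric(), z0_um = numeric(), x1_um = numeric(),
                  z1_um = numeric(), vx_mm_s = numeric(), vz_mm_s = numeric(),
                  speed_mm_s = numeric(), backscatter = numeric()))
  det <- arrange(det, .data$track_id, .data$frame)
  same <- det$track_id == lead(det$track_id, default = -1L)
  i0 <- which(same)
  bsc <- if ("backscatter" %in% names(det))
    (det$backscatter[i0] + det$backscatter[i0 + 1L]) / 2 else NA_real_
  tibble(track_id = det$track_id[i0], frame = det$frame[i0],
         t_s = det$frame[i0] / frame_rate,
         x0_um = det$x_um[i0], z0_um = det$z_um[i0],
         x1_um = det$x_um[i0 + 1L], z1_um = det$z_um[i0 + 1L],
         vx_mm_s = (det$x_um[i0 + 1L] - det$x_um[i0]) * frame_rate / 1000,
         vz_mm_s = (det$z_um[i0 + 1L] - det$z_um[i0]) * frame_rate / 1000,
         speed_mm_s = sqrt((det$x_um[i0 + 1L] - det$x_um[i0])^2 +
                           (det$z_um[i0 + 1L] - det$z_um[i0])^2) *
           frame_rate / 1000,
         backscatter = bsc)
}

#' Per-step velocity vectors of one track
#'
#' Successive positions compared to the previous one:
#' `v_i = (p_{i+1} - p_i) * frame_rate`, in mm/s, with `v_z > 0` pointing
#' down into the cortex.
#'
#' @param track tibble of one track's detections (`frame`, `x_um`, `z_um`),
#'   frame-consecutive.
#' @param frame_rate frames per second.
#' @return Tibble with one row per step: `vx_mm_s`, `vz_mm_s`, `speed_mm_s`.
#' @export
compute_velocities <- function(track, frame_rate) {
  if (nrow(track) < 2) abort("a track needs at least 2 detections")
  if (!"track_id" %in% names(track)) track$track_id <- 1L
  track_steps(track, frame_rate)
}

#' Rasterize track steps onto the fine grid
#'
#' Spatial linear interpolation along the track: every fine-grid pixel
#' crossed by the straight segment between two successive positions receives
#' one presence mark carrying the step's speed, velocity components and
#' backscatter. A pixel is marked at most once per step; a zero-length step
#' marks the occupied pixel.
#'
#' Each mark also records `step_px`, the number of pixels its step crossed:
#' a fixed pixel is touched by long steps more often than by short ones
#' (length-biased sampling), and downstream per-pixel velocity averages
#' weight marks by `1 / step_px` to undo that.
#'
#' @param steps a step table ([compute_velocities()] / `track_set$steps`).
#' @param grid a [grid_spec()].
#' @return Tibble of marks: `fine_col`, `fine_row` (0-based), `frame`,
#'   `t_s`, `speed_mm_s`, `vx_mm_s`, `vz_mm_s`, `backscatter`, `track_id`,
#'   `step_px`.
#' @export
rasterize_steps <- function(steps, grid) {
  fd <- fine_dim(grid); fp <- fine_pitch(grid)
  if (nrow(steps) == 0)
    return(tibble(fine_col = integer(), fine_row = integer(),
                  frame = integer(), t_s = numeric(), speed_mm_s = numeric(),
                  vx_mm_s = numeric(), vz_mm_s = numeric(),
                  backscatter = numeric(), track_id = integer(),
                  step_px = integer()))
  sc <- cpp_supercover(steps$x0_um / fp["x"], steps$z0_um / fp["z"],
                       steps$x1_um / fp["x"], steps$z1_um / fp["z"],
                       as.integer(fd["n_col"]), as.integer(fd["n_row"]))
  i <- sc$segment
  npx <- tabulate(i, nbins = nrow(steps))
  tibble(fine_col = sc$col, fine_row = sc$row,
         frame = steps$frame[i], t_s = steps$t_s[i],
         speed_mm_s = steps$speed_mm_s[i],
         vx_mm_s = steps$vx_mm_s[i], vz_mm_s = steps$vz_mm_s[i],
         backscatter = steps$backscatter[i], track_id = steps$track_id[i],
         step_px = npx[i])
}

#' @rdname rasterize_steps
#' @param track a single track's detections (`frame`, `x_um`, `z_um`).
#' @param frame_rate frames per second (single-track interface).
#' @export
rasterize_track <- function(track, grid, frame_rate) {
  if (nrow(track) == 1) {
    fp <- fine_pitch(grid)
    return(tibble(fine_col = as.integer(floor(track$x_um / fp["x"])),
                  fine_row = as.integer(floor(track$z_um / fp["z"])),
                  frame = track$frame, t_s = track$frame / frame_rate,
                  speed_mm_s = 0, vx_mm_s = 0, vz_mm_s = 0,
                  backscatter = if ("backscatter" %in% names(track))
                    track$backscatter else NA_real_,
                  track_id = 1L))
  }
  rasterize_steps(compute_velocities(track, frame_rate), grid)
}

#' All presence marks of a track set
#' @param tracks a `track_set`.
#' @param grid a [grid_spec()].
#' @return The concatenated mark table (see [rasterize_steps()]).
#' @export
ulm_marks <- function(tracks, grid) {
  rasterize_steps(tracks$steps, grid)
}

#' @export
tidy.track_set <- function(x, ...) x$steps

#' @export
glance.track_set <- function(x, ...) {
  tibble(n_tracks = length(unique(x$detections$track_id)),
         n_detections = x$counts$linked,
         n_discarded = x$counts$discarded_short,
         mean_speed_mm_s = mean(x$steps$speed_mm_s),
         frame_rate_hz = x$frame_rate)
}
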