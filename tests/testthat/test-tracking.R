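# brute-force optimal frame-to-frame assignment by enumeration (<= 4/frame)
brute_link <- function(prev, cur, gate) {
  m <- nrow(prev); k <- nrow(cur)
  D <- sqrt(outer(prev$x_um, cur$x_um, "-")^2 +
              outer(prev$z_um, cur$z_um, "-")^2)
  best <- NULL; best_cost <- Inf
  # enumerate all injective partial assignments
  opts <- lapply(seq_len(m), function(i) c(0L, seq_len(k)))
  grid <- do.call(expand.grid, opts)
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    used <- asg[asg > 0]
    if (anyDuplicated(used)) next
    cost <- 0
    ok <- TRUE
    for (i in seq_len(m)) {
      if (asg[i] > 0) {
        if (D[i, asg[i]] > gate) { ok <- FALSE; break }
        cost <- cost + D[i, asg[i]]
      } else cost <- cost + gate
    }
    cost <- cost + gate * (k - length(used))  # unmatched current
    if (ok && cost < best_cost) { best_cost <- cost; best <- asg }
  }
  best
}

test_that("a lone moving bubble forms one full-length track", {
  det <- tibble::tibble(frame = 0:9, x_um = 100 + 20 * (0:9), z_um = 500)
  ts <- link_tracks(det, 500)
  expect_equal(length(unique(ts$detections$track_id)), 1L)
  expect_equal(nrow(ts$detections), 10L)
  expect_equal(ts$steps$speed_mm_s, rep(10, 9))
})

test_that("the speed gate forbids overly fast links", {
  # 240 um in one frame at 500 Hz is 120 mm/s: beyond the 100 mm/s gate
  det <- tibble::tibble(frame = rep(0:5, each = 1),
                        x_um = c(0, 240, 480, 720, 960, 1200), z_um = 0)
  ts <- link_tracks(det, 500, max_speed_mm_s = 100, min_track_len = 1)
  expect_equal(length(unique(ts$detections$track_id)), 6L)
  # 199 um steps (99.5 mm/s) are allowed
  det2 <- tibble::tibble(frame = 0:5, x_um = 199 * (0:5), z_um = 0)
  ts2 <- link_tracks(det2, 500, max_speed_mm_s = 100, min_track_len = 1)
  expect_equal(length(unique(ts2$detections$track_id)), 1L)
})

test_that("tracks shorter than the minimum are discarded", {
  det <- tibble::tibble(frame = c(0:3, 0:5),
                        x_um = c(10 + 5 * (0:3), 2000 + 5 * (0:5)),
                        z_um = 100)
  ts <- link_tracks(det, 500, min_track_len = 5)
  expect_equal(length(unique(ts$detections$track_id)), 1L)
  expect_equal(ts$counts$discarded_short, 4L)
  expect_true(all(ts$detections$x_um >= 2000))
})

test_that("assignment matches exhaustive enumeration on crossing bubbles", {
  set.seed(4)
  gate <- 200
  for (rep in 1:20) {
    m <- sample(1:4, 1); k <- sample(1:4, 1)
    prev <- tibble::tibble(x_um = runif(m, 0, 400), z_um = runif(m, 0, 400))
    cur <- tibble::tibble(x_um = runif(k, 0, 400), z_um = runif(k, 0, 400))
    det <- dplyr::bind_rows(
      dplyr::mutate(prev, frame = 0L),
      dplyr::mutate(cur, frame = 1L))
    ts <- link_tracks(det, 500, max_speed_mm_s = 100, min_track_len = 1)
    dd <- ts$detections   # note: rows are re-sorted; match by coordinates
    id_prev <- vapply(seq_len(m), function(i)
      dd$track_id[dd$frame == 0L & dd$x_um == prev$x_um[i]][1], 0L)
    id_cur <- vapply(seq_len(k), function(j)
      dd$track_id[dd$frame == 1L & dd$x_um == cur$x_um[j]][1], 0L)
    got <- vapply(seq_len(m), function(i) {
      j <- which(id_cur == id_prev[i])
      if (length(j)) j else 0L
    }, 0L)
    want <- brute_link(prev, cur, gate)
    # both must achieve the same optimal total cost (ties may differ)
    cost_of <- function(asg) {
      D <- sqrt(outer(prev$x_um, cur$x_um, "-")^2 +
                  outer(prev$z_um, cur$z_um, "-")^2)
      c0 <- sum(vapply(seq_len(m), function(i)
        if (asg[i] > 0) D[i, asg[i]] else gate, 0))
      c0 + gate * (k - sum(asg > 0))
    }
    expect_equal(cost_of(got), cost_of(want), tolerance = 1e-9)
  }
})

test_that("two well-separated crossing bubbles are recovered exactly", {
  # bubbles cross in x while separated in z; steps << separation
  fr <- 0:19
  det <- dplyr::bind_rows(
    tibble::tibble(frame = fr, x_um = 100 + 15 * fr, z_um = 300),
    tibble::tibble(frame = fr, x_um = 400 - 15 * fr, z_um = 800))
  ts <- link_tracks(det, 500)
  expect_equal(length(unique(ts$detections$track_id)), 2L)
  byid <- split(ts$detections$z_um, ts$detections$track_id)
  expect_true(all(vapply(byid, function(z) length(unique(z)) == 1, TRUE)))
})

test_that("velocities follow the kinematic definition and sign convention", {
  track <- tibble::tibble(frame = 0:4, x_um = c(0, 12, 24, 36, 48),
                          z_um = c(0, 16, 32, 48, 64))
  v <- compute_velocities(track, 500)
  expect_equal(v$vx_mm_s, rep(6, 4))
  expect_equal(v$vz_mm_s, rep(8, 4))      # downward = positive
  expect_equal(v$speed_mm_s, rep(10, 4))
  # reversing the track negates the velocities
  rev_track <- tibble::tibble(frame = 0:4, x_um = rev(track$x_um),
                              z_um = rev(track$z_um))
  vr <- compute_velocities(rev_track, 500)
  expect_equal(vr$vx_mm_s, rep(-6, 4))
  expect_equal(vr$vz_mm_s, rep(-8, 4))
  expect_error(compute_velocities(track[1, ], 500), "at least 2")
})

test_that("descending arteriole ground truth yields v_z > 0 throughout", {
  lay <- single_vessel_layout(tilt_sd_deg = 4)
  tree <- build_vessel_tree(lay, seed = 21)
  gt <- simulate_tracks(tree, acq = acquisition_config(), seed = 22,
                        duration_s = 2)
  ts <- gt_track_set(gt)
  expect_gt(nrow(ts$steps), 50)
  expect_true(all(ts$steps$vz_mm_s > 0))
})

# brute-force pixel/segment intersection oracle for supercover rasterization
brute_cells <- function(x0, z0, x1, z1, n = 2e5) {
  t <- seq(0, 1, length.out = n)
  cells <- unique(cbind(floor(x0 + t * (x1 - x0)), floor(z0 + t * (z1 - z0))))
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

test_that("track rasterization marks exactly the crossed fine pixels", {
  g <- grid_spec(4, 4)   # 64 x 64 fine grid
  fp <- fine_pitch(g)
  # horizontal step spanning 5 fine pixels
  steps <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                          x0_um = 10.2 * fp[["x"]], z0_um = 7.5 * fp[["z"]],
                          x1_um = 14.7 * fp[["x"]], z1_um = 7.5 * fp[["z"]],
                          vx_mm_s = 1, vz_mm_s = 0, speed_mm_s = 1,
                          backscatter = 1)
  mk <- rasterize_steps(steps, g)
  expect_equal(nrow(mk), 5L)
  expect_equal(sort(mk$fine_col), 10:14)
  expect_equal(unique(mk$fine_row), 7L)
  expect_equal(unique(mk$speed_mm_s), 1)

  # zero-length step: one mark at the occupied pixel
  still <- tibble::tibble(frame = 0L, x_um = 3.4 * fp[["x"]],
                          z_um = 9.9 * fp[["z"]])
  mk0 <- rasterize_track(still, g, 500)
  expect_equal(nrow(mk0), 1L)
  expect_equal(c(mk0$fine_col, mk0$fine_row), c(3L, 9L))

  # diagonal steps match the brute-force supercover oracle
  set.seed(6)
  for (i in 1:25) {
    p <- runif(4, 2, 60)
    steps_d <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                              x0_um = p[1] * fp[["x"]], z0_um = p[2] * fp[["z"]],
                              x1_um = p[3] * fp[["x"]], z1_um = p[4] * fp[["z"]],
                              vx_mm_s = 0, vz_mm_s = 0, speed_mm_s = 1,
                              backscatter = NA)
    mk_d <- rasterize_steps(steps_d, g)
    got <- unique(cbind(mk_d$fine_col, mk_d$fine_row))
    want <- brute_cells(p[1], p[2], p[3], p[4])
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
    expect_false(any(duplicated(cbind(mk_d$fine_col, mk_d$fine_row))))
  }
})

test_that("emitted tracks never contain frame gaps", {
  set.seed(7)
  det <- tibble::tibble(frame = sort(sample(0:60, 120, replace = TRUE)),
                        x_um = runif(120, 0, 2000),
                        z_um = runif(120, 0, 2000))
  ts <- link_tracks(det, 500, min_track_len = 2)
  gaps <- tapply(ts$detections$frame, ts$detections$track_id,
                 function(f) any(diff(sort(f)) != 1))
  expect_false(any(gaps))
})
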