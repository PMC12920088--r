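mk_maps <- function(flow, g = grid_spec(2, 2)) {
  zero <- matrix(0, nrow(flow), ncol(flow))
  structure(list(mb_flow = flow, vx = zero, vz = zero, speed = zero,
                 backscatter = zero, window = c(0, 1), grid = g,
                 n_marks = sum(flow > 0)),
            class = "ulm_maps")
}

test_that("activation maps are relative increases, masked where undefined", {
  set.seed(31)
  base_flow <- matrix(runif(32 * 32), 32, 32)
  base_flow[1:5, ] <- 0
  b <- mk_maps(base_flow)
  s_same <- mk_maps(base_flow)
  am0 <- activation_map(b, s_same)
  expect_true(all(am0$values[am0$mask] == 0))
  s2 <- mk_maps(2 * base_flow)
  am2 <- activation_map(b, s2)
  expect_true(all(abs(am2$values[am2$mask] - 1) < 1e-12))
  expect_true(all(is.na(am2$values[!am2$mask])))
  expect_identical(am2$mask, base_flow > 0)
  expect_error(activation_map(b, mk_maps(matrix(1, 4, 4), grid_spec(4, 4))),
               "same grid")
  expect_equal(activation_increase(am2), 1)
})

test_that("injected flux gain is recovered in the activation map from
           ground-truth tracks", {
  lay <- scene_layout(n_arterioles = 2L, n_venules = 1L, n_act_branches = 2L,
                      arteriole_rate_mb_s = 8, act_rate_mb_s = 6)
  phen <- phenotype_params(activation_gain = 0.5, activation_rise_s = 0)
  prot <- stimulus_protocol(rest_s = 10, stim_s = 10, post_s = 0,
                            n_patterns = 12L)
  tree <- build_vessel_tree(lay, phen, seed = 61)
  gt <- simulate_tracks(tree, prot, acq = acquisition_config(), seed = 62,
                        duration_s = 240)
  ts <- gt_track_set(gt)
  grid <- scene_grid(lay)
  sp <- split_baseline_stim(ts, grid, prot)
  am <- activation_map(sp$baseline, sp$stimulation)
  # mask of the activated subtree from the true geometry
  fp <- fine_pitch(grid); fd <- fine_dim(grid)
  mask <- matrix(FALSE, fd[["n_row"]], fd[["n_col"]])
  for (i in which(tree$activated)) {
    cl <- tree$centerline[[i]]
    cum <- c(0, cumsum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)))
    s <- seq(0, max(cum), by = 3)
    xx <- approx(cum, cl[, 1], s)$y; zz <- approx(cum, cl[, 2], s)$y
    for (dx in -5:5) {
      cc <- pmin(pmax(floor(xx / fp[["x"]]) + 1 + dx, 1), fd[["n_col"]])
      rr <- pmin(pmax(floor(zz / fp[["z"]]) + 1, 1), fd[["n_row"]])
      mask[cbind(rr, cc)] <- TRUE
    }
  }
  rec <- activation_increase(am, mask)
  # Poisson oracle on the realized transits (the effective sample size):
  # occupancy gain of the activated subtree measured from ground truth
  d <- gt$detections[gt$detections$segment_id %in% tree$id[tree$activated], ]
  tp <- d$t_s %% 20
  occ_gain <- sum(tp >= 10) / sum(tp < 10) - 1
  expect_lt(abs(rec - occ_gain), 0.1)
  # outside the activated subtree the map is flat
  out <- activation_increase(am, !mask & am$mask)
  expect_lt(abs(out), 0.12)
})

test_that("depth-banded activation signals localize the responding zone", {
  lay <- scene_layout(n_arterioles = 2L, n_venules = 1L, n_act_branches = 4L,
                      arteriole_rate_mb_s = 8, act_rate_mb_s = 6,
                      activated_classes = "ACT")
  phen <- phenotype_params(activation_gain = 0.8, activation_rise_s = 0)
  prot <- stimulus_protocol(rest_s = 10, stim_s = 10, post_s = 0,
                            n_patterns = 10L)
  tree <- build_vessel_tree(lay, phen, seed = 63)
  gt <- simulate_tracks(tree, prot, acq = acquisition_config(), seed = 64,
                        duration_s = 200)
  ts <- gt_track_set(gt)
  grid <- scene_grid(lay)
  st <- dynamic_stack(ts, grid, prot, window_s = 2, duration_s = 200)
  pa <- pattern_average(st)
  mask <- matrix(TRUE, fine_dim(grid)[["n_row"]], fine_dim(grid)[["n_col"]])
  sig <- activation_signal(pa, mask, early_window_s = c(10, 16),
                           late_window_s = c(16, 20))
  metrics <- attr(sig, "metrics")
  deep <- metrics$early_increase_pct[metrics$band == "deep"]
  upper <- metrics$early_increase_pct[metrics$band == "upper"]
  # activation confined to the ACT zone: deep band responds far more
  expect_gt(deep, 3 * max(upper, 1))
  # baseline-window mean is 100% by construction
  base_mean <- mean(sig$signal_pct[sig$band == "deep" &
                                     sig$t_pattern_s < 10])
  expect_equal(base_mean, 100, tolerance = 1e-9)
  expect_error(activation_signal(pa, mask & FALSE), "empty")
})

test_that("a stationary scene yields a flat activation signal", {
  lay <- scene_layout(n_arterioles = 2L, n_venules = 1L, n_act_branches = 2L,
                      arteriole_rate_mb_s = 8, act_rate_mb_s = 6)
  prot <- stimulus_protocol(rest_s = 10, stim_s = 10, post_s = 0,
                            n_patterns = 8L)
  tree <- build_vessel_tree(lay, phenotype_params(), seed = 65)
  gt <- simulate_tracks(tree, prot, acq = acquisition_config(), seed = 66,
                        duration_s = 160)
  ts <- gt_track_set(gt)
  grid <- scene_grid(lay)
  pa <- pattern_average(dynamic_stack(ts, grid, prot, 2, 160))
  mask <- matrix(TRUE, fine_dim(grid)[["n_row"]], fine_dim(grid)[["n_col"]])
  sig <- activation_signal(pa, mask, early_window_s = c(10, 16),
                           late_window_s = c(16, 20))
  # tolerance ~3 Poisson standard errors of the transit counts
  m <- attr(sig, "metrics")
  expect_lt(max(abs(m$early_increase_pct)), 15)
  expect_lt(max(abs(m$late_increase_pct)), 15)
})

test_that("pattern QC applies the correlation, contralateral and 10% rules", {
  prot <- stimulus_protocol()        # 30/30/10, 35 windows of 2 s
  nw <- 35L
  tmid <- (seq_len(nw) - 0.5) * 2
  box <- as.numeric(tmid >= 30 & tmid < 60)
  set.seed(41)
  mk_sig <- function(gain, noise = 0.01) 100 * (1 + gain * box) +
    rnorm(nw, sd = noise)
  roi <- rbind(mk_sig(0.5), mk_sig(0.4), rnorm(nw, 100, 30), mk_sig(0.5))
  contra <- rbind(mk_sig(0), mk_sig(0.8), mk_sig(0), mk_sig(0))
  qc <- pattern_qc(roi, prot, contra_signals = contra)
  expect_true(qc$patterns$kept[1])
  # pattern 2: contralateral correlates with the stimulus -> rejected
  expect_false(qc$patterns$kept[2])
  expect_match(qc$patterns$reason[2], "contralateral")
  # pattern 3: noise, low stimulus correlation -> rejected
  expect_false(qc$patterns$kept[3])
  expect_gt(qc$mean_increase_pct, 10)
  expect_true(qc$acquisition_kept)

  # acquisition-level 10% rule: an 8% mean increase is rejected
  roi8 <- rbind(mk_sig(0.08 * 70 / 30), mk_sig(0.08 * 70 / 30))
  # construct signals whose stimulation-window mean increase is 8%
  roi8 <- rbind(100 * (1 + 0.08 * box), 100 * (1 + 0.08 * box))
  qc8 <- pattern_qc(roi8 + rnorm(2 * nw, sd = 0.01), prot)
  expect_lt(abs(qc8$mean_increase_pct - 8), 0.5)
  expect_false(qc8$acquisition_kept)

  # zero-variance signal is rejected with a reason
  qc0 <- pattern_qc(rbind(rep(100, nw), mk_sig(0.5)), prot)
  expect_false(qc0$patterns$kept[1])
  expect_match(qc0$patterns$reason[1], "zero-variance")

  # stability screen: wildly varying global flow fails the CV threshold
  glob <- rbind(rep(1000, nw), abs(rnorm(nw, 1000, 600)))
  qcg <- pattern_qc(rbind(mk_sig(0.5), mk_sig(0.5)), prot,
                    global_signals = glob)
  expect_true(qcg$patterns$kept[1])
  expect_false(qcg$patterns$kept[2])
  expect_match(qcg$patterns$reason[2], "unstable")
})

test_that("QC keeps everything for identical clean patterns", {
  prot <- stimulus_protocol(n_patterns = 5L)
  nw <- 35L
  tmid <- (seq_len(nw) - 0.5) * 2
  box <- as.numeric(tmid >= 30 & tmid < 60)
  roi <- matrix(rep(100 * (1 + 0.4 * box), 5), nrow = 5, byrow = TRUE)
  qc <- pattern_qc(roi, prot, contra_signals = matrix(rnorm(5 * nw, 100, 1),
                                                      5))
  expect_true(all(qc$patterns$kept))
  expect_true(qc$acquisition_kept)
})

test_that("track windows bundle tracks by first detection and conserve counts", {
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 15500:15520, x_um = 100 + 2 * (0:20), z_um = 50),
    tibble::tibble(frame = 16000:16010, x_um = 900 + 2 * (0:10), z_um = 250))
  ts <- link_tracks(det, 500)
  tw <- track_windows(ts, window_s = 4, t0 = 30)
  # a track starting at t = 31 s falls in the [30, 34) bundle
  expect_equal(tw$window[1], 0L)
  expect_equal(tw$window_start_s[1], 30)
  expect_equal(tw$window[2], 0L)
  expect_equal(nrow(tw), length(unique(ts$detections$track_id)))
  expect_error(track_windows(ts, window_s = 0), "positive")
  empty <- link_tracks(tibble::tibble(frame = integer(), x_um = numeric(),
                                      z_um = numeric()), 500)
  expect_equal(nrow(track_windows(empty)), 0L)
})
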