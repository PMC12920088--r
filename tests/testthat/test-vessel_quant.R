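# map-level fixtures built from ground truth (perfect localization), so
# these tests isolate the quantification stage from the imaging chain
gt_maps <- function(lay, seed, duration_s = 12, phen = phenotype_params()) {
  tree <- build_vessel_tree(lay, phen, seed = seed)
  gt <- simulate_tracks(tree, acq = acquisition_config(), seed = seed + 1,
                        duration_s = duration_s)
  ts <- gt_track_set(gt)
  list(maps = accumulate_maps(ts, scene_grid(lay), c(0, duration_s)),
       tree = tree, tracks = ts, grid = scene_grid(lay))
}

test_that("vesselness responds to a synthetic ridge and not to flat fields", {
  img <- matrix(0, 60, 60)
  img[, 30] <- 1; img[, 29] <- 0.6; img[, 31] <- 0.6   # vertical bright line
  v <- frangi_vesselness(img, scales = c(1, 2))
  expect_gt(max(v[10:50, 30]), 0.5)
  expect_lt(max(v[10:50, c(10:20, 40:50)]), 0.2)
  # constant interior gives no response (borders feel the zero padding)
  vf <- frangi_vesselness(matrix(1, 30, 30), 1:2)
  expect_lt(max(vf[10:20, 10:20]), 1e-6)
})

test_that("all-zero maps yield no vessel segments", {
  m <- accumulate_maps(tibble::tibble(fine_col = integer(),
                                      fine_row = integer(), frame = integer(),
                                      t_s = numeric(), speed_mm_s = numeric(),
                                      vx_mm_s = numeric(), vz_mm_s = numeric(),
                                      backscatter = numeric(),
                                      track_id = integer()),
                       grid_spec(6, 6), c(0, 1))
  expect_length(segment_vessels(m), 0L)
})

test_that("a straight vessel is segmented with an accurate centerline and class", {
  lay <- single_vessel_layout(tilt_sd_deg = 0)
  r <- gt_maps(lay, seed = 51)
  segs <- segment_vessels(r$maps, min_major_axis_um = 500)
  expect_equal(length(segs), 1L)
  expect_equal(segs[[1]]$class, "arteriole")   # descending flow
  # centerline within ~1 fine px of the true vertical line
  x_true <- r$tree$centerline[[1]][1, 1]
  cl <- segs[[1]]$centerline
  mid <- cl[cl[, "z_um"] > 300 & cl[, "z_um"] < 1900, ]
  expect_lt(median(abs(mid[, "x_um"] - x_true)), 7)
})

test_that("flow direction classifies arterioles vs venules without error", {
  lay <- scene_layout(n_arterioles = 2L, n_venules = 2L, n_act_branches = 0L)
  r <- gt_maps(lay, seed = 52)
  segs <- segment_vessels(r$maps, min_major_axis_um = 600)
  expect_gte(length(segs), 3L)
  for (s in segs) {
    expect_equal(s$class, if (s$mean_vz_mm_s > 0) "arteriole" else "venule")
    # verify against the nearest true vessel's flow direction
    x_mid <- median(s$centerline[, "x_um"])
    dists <- vapply(seq_len(nrow(r$tree)), function(i)
      min(abs(r$tree$centerline[[i]][, 1] - x_mid)), 0)
    true_class <- r$tree$class[which.min(dists)]
    expect_equal(s$class == "arteriole",
                 true_class %in% c("penetrating_arteriole", "ACT"))
  }
})

test_that("depth profiles are flat for constant-speed vessels", {
  lay <- single_vessel_layout(speed_mm_s = 8, tilt_sd_deg = 2)
  r <- gt_maps(lay, seed = 53, duration_s = 16)
  segs <- segment_vessels(r$maps, min_major_axis_um = 500)
  p <- depth_profile(r$maps, segs[[1]])
  # upper part (above the ACT transition) flows at the arteriole speed
  up <- p$speed_mm_s[p$depth_um > 100 & p$depth_um < 380]
  expect_lt(abs(mean(up) - 8) / 8, 0.05)
  # below 400 um the ACT continuation is slower (4 mm/s default)
  deep <- p$speed_mm_s[p$depth_um > 600 & p$depth_um < 2000 & p$speed_mm_s > 0]
  expect_lt(abs(mean(deep) - 4) / 4, 0.1)
  expect_error(depth_profile(r$maps, list(z_range_um = c(0, 20),
                                          centerline = segs[[1]]$centerline)),
               "too few depth steps")
})

test_that("profiles of empty regions are zero", {
  lay <- single_vessel_layout()
  r <- gt_maps(lay, seed = 54, duration_s = 4)
  fake <- list(centerline = cbind(x_um = c(2700, 2700), z_um = c(100, 2000)),
               z_range_um = c(100, 2000), mask = NULL)
  p <- depth_profile(r$maps, fake)
  expect_true(all(p$speed_mm_s == 0))
  expect_true(all(p$mb_flow == 0))
})

test_that("backscatter FWHM recovers diameters to about one fine pixel", {
  for (d_um in c(28, 40)) {
    lay <- single_vessel_layout(diameter_um = d_um, rate_mb_s = 10,
                                tilt_sd_deg = 0)
    r <- gt_maps(lay, seed = 55 + d_um, duration_s = 20)
    # the measured stretch is the 28-um-class upper segment (60-400 um)
    segs <- segment_vessels(r$maps, min_major_axis_um = 300)
    dd <- vapply(seq(140, 360, by = 20), function(z) {
      m <- measure_diameter(r$maps$backscatter, segs[[1]], z, r$grid)
      if (m$flagged) NA_real_ else m$diameter_um
    }, 0)
    # marks fill 98% of the lumen; pixelization adds about one fine px
    expect_lt(abs(median(dd, na.rm = TRUE) - 0.98 * d_um), 7)
  }
})

test_that("degenerate diameter profiles are flagged with a reason", {
  g <- grid_spec(4, 4)
  seg <- list(centerline = cbind(x_um = c(200, 200), z_um = c(50, 400)),
              z_range_um = c(50, 400))
  zero <- matrix(0, 64, 64)
  m <- measure_diameter(zero, seg, 200, g)
  expect_true(m$flagged)
  expect_match(m$reason, "empty")
  flat <- matrix(1, 64, 64)
  m2 <- measure_diameter(flat, seg, 200, g)
  expect_true(m2$flagged)
})

test_that("tortuosity is zero for straight flow and matches the analytic
           tangent-angle spread for sinusoidal vessels", {
  # straight constant-direction track steps
  straight <- list(steps = tibble::tibble(
    track_id = 1L, frame = 0:19, t_s = 0,
    x0_um = 50 * (0:19), z0_um = 100 + 10 * (0:19),
    x1_um = 50 * (1:20), z1_um = 100 + 10 * (1:20),
    vx_mm_s = 25, vz_mm_s = 5,
    speed_mm_s = sqrt(25^2 + 5^2), backscatter = NA))
  seg <- list(mask = NULL)
  t0 <- tortuosity(seg, straight, grid_spec(4, 4))
  expect_equal(t0$value, 0, tolerance = 1e-6)

  # sinusoidal centerline: amplitude 30 um, wavelength 300 um
  A <- 30; lam <- 300
  z <- seq(0, 1200, by = 4)
  x <- 500 + A * sin(2 * pi * z / lam)
  steps <- tibble::tibble(
    track_id = 1L, frame = seq_along(z)[-length(z)], t_s = 0,
    x0_um = x[-length(x)], z0_um = z[-length(z)],
    x1_um = x[-1], z1_um = z[-1],
    vx_mm_s = diff(x) * 0.5, vz_mm_s = diff(z) * 0.5,
    speed_mm_s = sqrt(diff(x)^2 + diff(z)^2) * 0.5, backscatter = NA)
  ts <- list(steps = steps)
  tort <- tortuosity(seg, ts, grid_spec(4, 4))
  # oracle: circular std of tangent angles from dense numeric
  # differentiation of the analytic centerline, arc-length weighted
  zf <- seq(0, 1200, by = 0.25)
  xf <- 500 + A * sin(2 * pi * zf / lam)
  th <- atan2(diff(zf), diff(xf))
  w <- sqrt(diff(zf)^2 + diff(xf)^2)
  R <- sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
  expected <- sqrt(-2 * log(R))
  expect_lt(abs(tort$value - expected) / expected, 0.1)

  # rotation invariance
  phi <- 0.7
  rot <- dplyr::mutate(steps,
    vx2 = cos(phi) * vx_mm_s - sin(phi) * vz_mm_s,
    vz2 = sin(phi) * vx_mm_s + cos(phi) * vz_mm_s,
    vx_mm_s = vx2, vz_mm_s = vz2)
  tr <- tortuosity(seg, list(steps = rot), grid_spec(4, 4))
  expect_equal(tr$value, tort$value, tolerance = 1e-9)
})

test_that("tortuosity increases strictly with perturbation amplitude", {
  vals <- vapply(c(5, 15, 30, 60), function(A) {
    z <- seq(0, 1200, by = 4)
    x <- 500 + A * sin(2 * pi * z / 300)
    steps <- tibble::tibble(
      track_id = 1L, frame = seq_along(z)[-length(z)], t_s = 0,
      x0_um = x[-length(x)], z0_um = z[-length(z)],
      x1_um = x[-1], z1_um = z[-1],
      vx_mm_s = diff(x) * 0.5, vz_mm_s = diff(z) * 0.5,
      speed_mm_s = sqrt(diff(x)^2 + diff(z)^2) * 0.5, backscatter = NA)
    tortuosity(list(mask = NULL), list(steps = steps), grid_spec(4, 4))$value
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("short tracks are excluded from tortuosity by the length filter", {
  # a 90 um track against the 100 um (0.1 mm) filter
  short <- tibble::tibble(
    track_id = 1L, frame = 0:8, t_s = 0,
    x0_um = 10 * (0:8), z0_um = 0, x1_um = 10 * (1:9), z1_um = 0,
    vx_mm_s = 5, vz_mm_s = 0, speed_mm_s = 5, backscatter = NA)
  expect_error(tortuosity(list(mask = NULL), list(steps = short),
                          grid_spec(4, 4)),
               "100")
  # scalar-product variant runs on qualifying tracks
  long <- dplyr::mutate(short, x0_um = 20 * (0:8), x1_um = 20 * (1:9))
  ts <- tortuosity(list(mask = NULL), list(steps = long), grid_spec(4, 4),
                   mode = "scalar")
  expect_equal(ts$value, 0, tolerance = 1e-12)
})

test_that("roundness follows 4A/(pi M^2)", {
  r <- 7
  expect_equal(roundness(pi * r^2, 2 * r), 1)
  # ellipse with full axes a > b: area pi a b / 4, roundness b/a
  a <- 12; b <- 5
  expect_equal(roundness(pi * a * b / 4, a), b / a)
  expect_error(roundness(0, 3), "positive")
  expect_error(roundness(3, -1), "positive")
})
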