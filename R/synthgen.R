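#' Phenotype parameters for the synthetic vascular scene
#'
#' Knobs that turn a control scene into a phenotype scene: uniform dilation
#' of arteriolar diameters, slowed arteriolar / arteriole-capillary
#' transition (ACT) flow, sinusoidal centerline tortuosity, and a blunted or
#' delayed stimulus-evoked increase of microbubble flux in the activated
#' subtree.
#'
#' @param dilation_factor multiplies arteriole/ACT diameters (control 1.0).
#' @param speed_factor_arteriole,speed_factor_act multiply mean flow speeds.
#' @param tortuosity_amplitude_um,tortuosity_wavelength_um sinusoidal
#'   centerline perturbation (um); amplitude 0 keeps vessels straight.
#' @param activation_gain fractional flux increase during stimulation in
#'   activated segments (0.5 = +50%).
#' @param activation_delay_s delay of the flux increase after stimulus onset.
#' @param activation_rise_s linear ramp duration of the flux increase.
#' @param activation_overshoot if `TRUE`, the response overshoots by
#'   `overshoot_gain` and settles with time constant `overshoot_tau_s`.
#' @param overshoot_gain,overshoot_tau_s overshoot shape parameters.
#' @param amplitude_sdlog log-normal spread of per-bubble echo amplitudes.
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(dilation_factor = 1,
                             speed_factor_arteriole = 1,
                             speed_factor_act = 1,
                             tortuosity_amplitude_um = 0,
                             tortuosity_wavelength_um = 300,
                             activation_gain = 0,
                             activation_delay_s = 0,
                             activation_rise_s = 2,
                             activation_overshoot = FALSE,
                             overshoot_gain = 0.5,
                             overshoot_tau_s = 5,
                             amplitude_sdlog = 0.25) {
  stopifnot(dilation_factor > 0, speed_factor_arteriole > 0,
            speed_factor_act > 0, tortuosity_amplitude_um >= 0,
            tortuosity_wavelength_um > 0, activation_delay_s >= 0,
            activation_rise_s >= 0)
  structure(as.list(environment()), class = "phenotype_params")
}

#' Tissue clutter parameters
#'
#' Emulates the low-rank, high-amplitude tissue signal that the SVD clutter
#' filter removes: `rank` smooth spatial modes whose temporal envelopes mix
#' a quasi-static baseline with distinct physiological motion frequencies
#' (a mouse-cardiac fundamental of `cardiac_hz` and harmonics spaced
#' `mode_spacing_hz` apart), at
#' `clutter_to_bubble_db` decibels above the reference bubble amplitude
#' (RMS), plus additive white noise. The distinct frequencies keep the
#' tissue modes linearly independent within a processing block, as real
#' pulsatile tissue motion is, so a rank-matched SVD cut removes them
#' cleanly.
#'
#' @param rank number of clutter modes (must stay below the block size).
#' @param clutter_to_bubble_db clutter RMS over median bubble peak, dB.
#' @param drift_period_s period of the slow baseline drift of mode 1.
#' @param cardiac_hz cardiac fundamental of the pulsatile modes (a mouse
#'   heart beats at 500-700 min^-1, i.e. 8-12 Hz).
#' @param mode_spacing_hz frequency spacing of the motion harmonics.
#' @param noise_sigma additive white-noise standard deviation (bubble peak
#'   amplitude is ~1, so `noise_sigma = 0.1` is 20 dB SNR).
#' @return A `clutter_params` list.
#' @export
clutter_params <- function(rank = 5L, clutter_to_bubble_db = 30,
                           drift_period_s = 10, cardiac_hz = 10,
                           mode_spacing_hz = 4, noise_sigma = 0) {
  stopifnot(rank >= 0, is.finite(clutter_to_bubble_db), noise_sigma >= 0)
  structure(list(rank = as.integer(rank),
                 clutter_to_bubble_db = clutter_to_bubble_db,
                 drift_period_s = drift_period_s,
                 cardiac_hz = cardiac_hz,
                 mode_spacing_hz = mode_spacing_hz,
                 noise_sigma = noise_sigma),
            class = "clutter_params")
}

#' Default desk-scale scene layout
#'
#' A 3 x 3 mm cortical field with descending penetrating arterioles that
#' continue below `act_depth_threshold_um` as slower ACT segments (plus short
#' lateral ACT offshoots) and ascending venules. One arteriolar subtree is
#' flagged as the stimulus-activated territory.
#'
#' @param field_width_um,field_depth_um field of view, um.
#' @param n_arterioles,n_venules,n_act_branches vessel counts.
#' @param arteriole_diameter_um,act_diameter_um,venule_diameter_um diameters.
#' @param arteriole_speed_mm_s,act_speed_mm_s,venule_speed_mm_s mean speeds.
#' @param arteriole_rate_mb_s,act_rate_mb_s,venule_rate_mb_s baseline
#'   microbubble flux per segment, MBs/s.
#' @param act_depth_threshold_um depth splitting arteriole from ACT zone.
#' @param tilt_sd_deg standard deviation of the random off-vertical tilt of
#'   penetrating vessels (real penetrating vessels are only roughly
#'   vertical; parallel identical vessels would also make the microbubble
#'   signal unrealistically low-rank in space-time).
#' @param activated_arteriole index of the activated arteriolar subtree.
#' @param activated_classes classes that respond to stimulation within the
#'   activated subtree.
#' @return A `scene_layout` list.
#' @export
scene_layout <- function(field_width_um = 3000, field_depth_um = 3000,
                         n_arterioles = 5L, n_venules = 2L,
                         n_act_branches = 8L,
                         arteriole_diameter_um = 28, act_diameter_um = 10,
                         venule_diameter_um = 30,
                         arteriole_speed_mm_s = 10, act_speed_mm_s = 4,
                         venule_speed_mm_s = 5,
                         arteriole_rate_mb_s = 3, act_rate_mb_s = 1.5,
                         venule_rate_mb_s = 2,
                         act_depth_threshold_um = 400,
                         tilt_sd_deg = 6,
                         activated_arteriole = 1L,
                         activated_classes = c("penetrating_arteriole", "ACT")) {
  structure(as.list(environment()), class = "scene_layout")
}

resample_polyline <- function(pts, step_um = 25) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  if (L == 0) return(pts)
  s <- seq(0, L, by = step_um)
  if (L - s[length(s)] < step_um / 2) s <- s[-length(s)]
  s <- c(s, L)
  cbind(x = approx(cl, pts[, 1], s)$y, z = approx(cl, pts[, 2], s)$y)
}

polyline_length <- function(pts) {
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

make_segment <- function(id, class, centerline, diameter_um, speed_mm_s,
                         rate_mb_s, parent = NA_integer_,
                         flow_direction = 1L, activated = FALSE) {
  tibble(id = as.integer(id), class = class, parent = as.integer(parent),
         diameter_um = diameter_um, speed_mm_s = speed_mm_s,
         rate_mb_s = rate_mb_s, flow_direction = as.integer(flow_direction),
         activated = activated, centerline = list(centerline))
}

#' Assemble a vessel tree from segment rows
#'
#' Validates geometry against the field of view and the class flow
#' conventions (descending arterioles `v_z > 0`, ascending venules
#' `v_z < 0`, ACT segments below the depth threshold).
#'
#' @param segments tibble of segment rows (see [build_vessel_tree()]).
#' @param layout a [scene_layout()] (used for the field of view).
#' @param phenotype the [phenotype_params()] the tree was built with.
#' @return A `vessel_tree` tibble.
#' @export
vessel_tree <- function(segments, layout = scene_layout(),
                        phenotype = phenotype_params()) {
  ext <- c(layout$field_width_um, layout$field_depth_um)
  for (i in seq_len(nrow(segments))) {
    cl <- segments$centerline[[i]]
    if (any(cl[, 1] < 0 | cl[, 1] > ext[1] | cl[, 2] < 0 | cl[, 2] > ext[2]))
      abort(sprintf("segment %d (%s) exceeds the field of view",
                    segments$id[i], segments$class[i]))
    if (segments$diameter_um[i] <= 0 || segments$speed_mm_s[i] < 0)
      abort(sprintf("segment %d has invalid diameter or speed",
                    segments$id[i]))
  }
  structure(segments, class = c("vessel_tree", class(tibble())),
            layout = layout, phenotype = phenotype)
}

#' Build the synthetic cortical vessel tree
#'
#' Deterministic for a fixed seed. Phenotype knobs are applied here:
#' diameters are multiplied by `dilation_factor` (arteriole/ACT classes),
#' speeds by the class speed factors, and arteriolar centerlines are
#' perturbed laterally by a sinusoid when `tortuosity_amplitude_um > 0`.
#' Child segments start at a parent vertex.
#'
#' @param layout a [scene_layout()].
#' @param phenotype a [phenotype_params()].
#' @param seed integer RNG seed.
#' @return A `vessel_tree` tibble with one row per segment and a
#'   `centerline` list-column of `(x, z)` um polylines ordered top-down;
#'   `flow_direction` is +1 when flow follows the stored order.
#' @export
build_vessel_tree <- function(layout = scene_layout(),
                              phenotype = phenotype_params(), seed = 1L) {
  with_seed(seed, {
    lay <- layout; phen <- phenotype
    n_slots <- lay$n_arterioles + lay$n_venules
    margin <- max(300, lay$field_width_um * 0.1)
    xs <- margin + (seq_len(n_slots) - 0.5) / n_slots *
      (lay$field_width_um - 2 * margin)
    art_slots <- round(seq(1, n_slots, length.out = lay$n_arterioles))
    ven_slots <- setdiff(seq_len(n_slots), art_slots)[seq_len(lay$n_venules)]
    z_top <- 60
    z_deep <- min(lay$field_depth_um - 300, 2200)
    z_split <- lay$act_depth_threshold_um
    perturb <- function(pts, phase) {
      if (phen$tortuosity_amplitude_um <= 0) return(pts)
      s <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
      pts[, 1] <- pts[, 1] + phen$tortuosity_amplitude_um *
        sin(2 * pi * s / phen$tortuosity_wavelength_um + phase)
      pts
    }
    segs <- list(); nid <- 0L
    act_parents <- list()
    tilt_of <- function(x0) {
      th <- rnorm(1, 0, lay$tilt_sd_deg * pi / 180)
      # keep the deep end inside the lateral field margins
      dxmax <- (z_deep - z_top) * tan(abs(th)) + 1e-9
      room <- if (th > 0) lay$field_width_um - 60 - x0 else x0 - 60
      th * min(1, max(0, room) / dxmax)
    }
    for (k in seq_len(lay$n_arterioles)) {
      x <- xs[art_slots[k]]
      phase <- runif(1, 0, 2 * pi)
      th <- tilt_of(x)
      up <- resample_polyline(cbind(
        x = c(x, x + (z_split - z_top) * tan(th)), z = c(z_top, z_split)))
      up <- perturb(up, phase)
      nid <- nid + 1L; up_id <- nid
      segs[[nid]] <- make_segment(nid, "penetrating_arteriole", up,
        lay$arteriole_diameter_um * phen$dilation_factor,
        lay$arteriole_speed_mm_s * phen$speed_factor_arteriole,
        lay$arteriole_rate_mb_s,
        activated = k == lay$activated_arteriole &&
          "penetrating_arteriole" %in% lay$activated_classes)
      s_up <- c(0, cumsum(sqrt(diff(up[, 1])^2 + diff(up[, 2])^2)))
      x_sp <- x + (z_split - z_top) * tan(th)
      trunk <- resample_polyline(cbind(
        x = c(x_sp, x_sp + (z_deep - z_split) * tan(th)),
        z = c(z_split, z_deep)))
      trunk <- perturb(trunk, phase + 2 * pi * max(s_up) /
                         phen$tortuosity_wavelength_um)
      trunk[1, ] <- up[nrow(up), ]  # child starts at a parent vertex
      nid <- nid + 1L
      segs[[nid]] <- make_segment(nid, "ACT", trunk,
        lay$act_diameter_um * phen$dilation_factor,
        lay$act_speed_mm_s * phen$speed_factor_act,
        lay$act_rate_mb_s, parent = up_id,
        activated = k == lay$activated_arteriole &&
          "ACT" %in% lay$activated_classes)
      act_parents[[k]] <- list(id = nid, pts = trunk,
                               activated = k == lay$activated_arteriole)
    }
    for (b in seq_len(lay$n_act_branches)) {
      k <- ((b - 1L) %% lay$n_arterioles) + 1L
      tr <- act_parents[[k]]
      depth <- runif(1, z_split + 150, z_deep - 500)
      i0 <- which.min(abs(tr$pts[, 2] - depth))
      p0 <- tr$pts[i0, ]
      dir <- if (b %% 2 == 0) 1 else -1
      len <- 400
      ang <- 35 * pi / 180
      p1 <- p0 + len * c(dir * cos(ang), sin(ang))
      p1[1] <- min(max(p1[1], 30), lay$field_width_um - 30)
      br <- resample_polyline(rbind(p0, p1))
      nid <- nid + 1L
      segs[[nid]] <- make_segment(nid, "ACT", br,
        lay$act_diameter_um * phen$dilation_factor,
        lay$act_speed_mm_s * phen$speed_factor_act,
        lay$act_rate_mb_s, parent = tr$id,
        activated = tr$activated && "ACT" %in% lay$activated_classes)
    }
    for (k in seq_len(lay$n_venules)) {
      x <- xs[ven_slots[k]]
      thv <- tilt_of(x)
      ven <- resample_polyline(cbind(
        x = c(x, x + (z_deep - z_top) * tan(thv)), z = c(z_top, z_deep)))
      nid <- nid + 1L
      segs[[nid]] <- make_segment(nid, "venule", ven,
        lay$venule_diameter_um, lay$venule_speed_mm_s, lay$venule_rate_mb_s,
        flow_direction = -1L)
    }
    vessel_tree(bind_rows(segs), layout = lay, phenotype = phen)
  })
}

#' Stimulus-evoked flux envelope
#'
#' Normalized activation envelope e(t) in `[0, 1+overshoot]` as a function of
#' pattern-relative time: 0 during baseline, a linear ramp of
#' `activation_rise_s` starting `activation_delay_s` after stimulus onset,
#' an optional decaying overshoot, and a symmetric ramp down after stimulus
#' offset. The segment flux multiplier is `1 + activation_gain * e(t)`.
#'
#' @param t_pattern_s pattern-relative times, s.
#' @param protocol a [stimulus_protocol()].
#' @param phenotype a [phenotype_params()].
#' @return Numeric vector of envelope values.
#' @export
activation_envelope <- function(t_pattern_s, protocol, phenotype) {
  onset <- protocol$rest_s + phenotype$activation_delay_s
  off <- protocol$rest_s + protocol$stim_s
  rise <- max(phenotype$activation_rise_s, 1e-9)
  up <- pmin(pmax((t_pattern_s - onset) / rise, 0), 1)
  down <- pmin(pmax((t_pattern_s - off) / rise, 0), 1)
  e <- pmax(up - down, 0)
  if (isTRUE(phenotype$activation_overshoot)) {
    dt <- pmax(t_pattern_s - onset - rise, 0)
    e <- e * (1 + phenotype$overshoot_gain *
                exp(-dt / phenotype$overshoot_tau_s))
  }
  e
}

flux_multiplier <- function(t_s, protocol, phenotype, activated) {
  if (!activated || phenotype$activation_gain == 0)
    return(rep(1, length(t_s)))
  P <- pattern_duration(protocol)
  tp <- t_s %% P
  m <- 1 + phenotype$activation_gain * activation_envelope(tp, protocol,
                                                           phenotype)
  m[t_s < 0] <- 1
  m
}

#' Simulate ground-truth microbubble transits
#'
#' Bubble entries per segment follow a Poisson process (rate =
#' `rate_mb_s` times the stimulation flux multiplier, simulated by thinning);
#' each bubble advances along the segment centerline at its own speed —
#' the segment mean times a log-normal factor of coefficient of variation
#' `speed_jitter_cv` (flow is faster near the lumen centre than at the
#' wall), with unit mean so segment-mean speeds are preserved — with a
#' constant lateral offset drawn uniformly inside the vessel lumen, and
#' carries a log-normal echo amplitude. Entries are drawn from one transit
#' time before t = 0 so the scene starts in steady state.
#'
#' @param tree a [build_vessel_tree()] result.
#' @param protocol a [stimulus_protocol()].
#' @param phenotype a [phenotype_params()]; defaults to the tree's.
#' @param acq an [acquisition_config()].
#' @param seed integer RNG seed.
#' @param duration_s simulated duration; defaults to `acq$duration_s`, else
#'   the full protocol duration.
#' @param speed_jitter_cv per-bubble speed coefficient of variation.
#' @return A `ground_truth` object with per-frame bubble positions
#'   (`$detections`), per-bubble entry times (`$entries`) and the inputs.
#' @export
simulate_tracks <- function(tree, protocol = stimulus_protocol(),
                            phenotype = NULL, acq = acquisition_config(),
                            seed = 1L, duration_s = NULL,
                            speed_jitter_cv = 0.1) {
  if (is.null(phenotype)) phenotype <- attr(tree, "phenotype")
  if (is.null(phenotype)) phenotype <- phenotype_params()
  if (is.null(duration_s))
    duration_s <- if (!is.null(acq$duration_s)) acq$duration_s
                  else protocol_duration(protocol)
  fr <- acq$frame_rate_hz
  m_max <- 1 + max(0, phenotype$activation_gain) *
    (1 + if (isTRUE(phenotype$activation_overshoot))
      phenotype$overshoot_gain else 0)
  with_seed(seed, {
    det <- list(); ent <- list(); next_track <- 1L
    for (i in seq_len(nrow(tree))) {
      seg <- tree[i, ]
      if (seg$rate_mb_s <= 0 || seg$speed_mm_s <= 0) next
      pts <- seg$centerline[[1]]
      if (seg$flow_direction < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
      d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
      cl <- c(0, cumsum(d)); L <- cl[length(cl)]
      Tt0 <- L / (seg$speed_mm_s * 1000)
      rmax <- seg$rate_mb_s * if (seg$activated) m_max else 1
      lead_s <- 1.6 * Tt0   # cover slow-jittered bubbles already in transit
      n_cand <- rpois(1, rmax * (duration_s + lead_s))
      if (n_cand == 0) next
      t0 <- sort(runif(n_cand, -lead_s, duration_s))
      keep <- runif(n_cand) < seg$rate_mb_s *
        flux_multiplier(t0, protocol, phenotype, seg$activated) / rmax
      t0 <- t0[keep]
      nb <- length(t0)
      if (nb == 0) next
      ids <- next_track + seq_len(nb) - 1L
      next_track <- next_track + nb
      amp <- exp(rnorm(nb, 0, phenotype$amplitude_sdlog))
      off <- runif(nb, -0.49, 0.49) * seg$diameter_um
      cv <- speed_jitter_cv
      v_b <- seg$speed_mm_s * exp(rnorm(nb, -cv^2 / 2, cv))  # unit mean
      Tt_b <- L / (v_b * 1000)
      k0 <- pmax(0L, as.integer(ceiling(t0 * fr - 1e-9)))
      k1 <- pmin(as.integer(floor(duration_s * fr - 1e-9)),
                 as.integer(floor((t0 + Tt_b) * fr + 1e-9)))
      nk <- pmax(0L, k1 - k0 + 1L)
      use <- nk > 0
      if (!any(use)) next
      frames <- unlist(lapply(which(use), function(j) k0[j]:k1[j]))
      bid <- rep(which(use), nk[use])
      tk <- frames / fr
      s <- (tk - t0[bid]) * v_b[bid] * 1000
      s <- pmin(pmax(s, 0), L)
      x <- approx(cl, pts[, 1], s)$y
      z <- approx(cl, pts[, 2], s)$y
      ds <- pmin(5, L / 2)
      tx <- approx(cl, pts[, 1], pmin(s + ds, L))$y -
            approx(cl, pts[, 1], pmax(s - ds, 0))$y
      tz <- approx(cl, pts[, 2], pmin(s + ds, L))$y -
            approx(cl, pts[, 2], pmax(s - ds, 0))$y
      tn <- sqrt(tx^2 + tz^2); tn[tn == 0] <- 1
      tx <- tx / tn; tz <- tz / tn
      det[[length(det) + 1L]] <- tibble(
        frame = as.integer(frames), t_s = tk,
        track_id = ids[bid], segment_id = seg$id,
        x_um = x + off[bid] * (-tz), z_um = z + off[bid] * tx,
        vx_mm_s = v_b[bid] * tx, vz_mm_s = v_b[bid] * tz,
        speed_mm_s = v_b[bid], amplitude = amp[bid])
      ent[[length(ent) + 1L]] <- tibble(segment_id = seg$id, track_id = ids,
                                        t_entry_s = t0)
    }
    detections <- if (length(det)) arrange(bind_rows(det), .data$frame,
                                           .data$track_id) else
      tibble(frame = integer(), t_s = numeric(), track_id = integer(),
             segment_id = integer(), x_um = numeric(), z_um = numeric(),
             vx_mm_s = numeric(), vz_mm_s = numeric(),
             speed_mm_s = numeric(), amplitude = numeric())
    structure(list(detections = detections,
                   entries = if (length(ent)) bind_rows(ent) else
                     tibble(segment_id = integer(), track_id = integer(),
                            t_entry_s = numeric()),
                   tree = tree, protocol = protocol, phenotype = phenotype,
                   acq = acq, duration_s = duration_s, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d bubbles, %d frame-positions over %g s\n",
              nrow(x$entries), nrow(x$detections), x$duration_s))
  invisible(x)
}

#' Grid matching a scene layout
#' @param layout a [scene_layout()].
#' @param ... passed to [grid_spec()].
#' @return A [grid_spec()] whose native field of view covers the layout.
#' @export
scene_grid <- function(layout = scene_layout(), ...) {
  g <- grid_spec(n_x_native = 1, n_z_native = 1, ...)
  grid_spec(n_x_native = ceiling(layout$field_width_um / g$native_pitch_x),
            n_z_native = ceiling(layout$field_depth_um / g$native_pitch_z),
            native_pitch_x = g$native_pitch_x,
            native_pitch_z = g$native_pitch_z,
            fine_factor = g$fine_factor, interp_factor = g$interp_factor)
}

upsample_bilinear <- function(m, nr, nc) {
  r0 <- seq(0, 1, length.out = nrow(m)); c0 <- seq(0, 1, length.out = ncol(m))
  r1 <- seq(0, 1, length.out = nr); c1 <- seq(0, 1, length.out = nc)
  tmp <- apply(m, 2, function(col) approx(r0, col, r1)$y)
  t(apply(tmp, 1, function(row) approx(c0, row, c1)$y))
}

#' Render ultrafast frames from ground truth
#'
#' Forward model of the acquisition: each frame is the sum of `rank` smooth
#' low-rank clutter modes with slow temporal envelopes, the bubbles' 2D
#' Gaussian point-spread echoes at their true subpixel positions, and white
#' noise. Deterministic for a fixed seed.
#'
#' @param gt a [simulate_tracks()] result.
#' @param grid a [grid_spec()]; defaults to [scene_grid()] of the tree layout.
#' @param clutter a [clutter_params()].
#' @param seed integer RNG seed (clutter and noise).
#' @param psf_sigma_um isotropic PSF width (Gaussian sigma); the default
#'   corresponds to a full width at half maximum of 1.8 wavelengths
#'   (about 79 um sigma at 15 MHz, an f/1.8 transcranial aperture) —
#'   diffraction-scale, and wide enough that sampling on the
#'   one-wavelength native pitch neither aliases nor grid-locks the
#'   localized positions.
#' @return A raw [frame_stack()].
#' @export
render_frames <- function(gt, grid = NULL, clutter = clutter_params(),
                          seed = 1L, psf_sigma_um = NULL) {
  acq <- gt$acq
  if (is.null(grid)) grid <- scene_grid(attr(gt$tree, "layout"))
  if (clutter$rank >= acq$block_size)
    abort("clutter rank must be below the block size")
  if (is.null(psf_sigma_um))
    psf_sigma_um <- default_psf_sigma_um(acq)
  nz <- grid$n_z_native; nx <- grid$n_x_native
  nf <- as.integer(round(gt$duration_s * acq$frame_rate_hz))
  det <- gt$detections
  out <- cpp_stamp_bubbles(nz, nx, nf, det$frame,
                           det$z_um / grid$native_pitch_z,
                           det$x_um / grid$native_pitch_x,
                           det$amplitude,
                           psf_sigma_um / grid$native_pitch_z,
                           psf_sigma_um / grid$native_pitch_x, 4)
  with_seed(seed, {
    if (clutter$rank > 0) {
      target_rms <- 10^(clutter$clutter_to_bubble_db / 20)
      U <- matrix(0, nz * nx, clutter$rank)
      A <- matrix(0, clutter$rank, nf)
      t_s <- (seq_len(nf) - 1L) / acq$frame_rate_hz
      for (r in seq_len(clutter$rank)) {
        coarse <- matrix(rnorm(36), 6, 6)
        u <- upsample_bilinear(coarse, nz, nx)
        U[, r] <- as.vector(u) / sqrt(mean(u^2))
        # mode 1: quasi-static drift; higher modes: cardiac harmonics
        # above the slow-bubble band
        f_r <- if (r == 1) 0 else
          clutter$cardiac_hz + (r - 2) * clutter$mode_spacing_hz
        A[r, ] <- cos(2 * pi * (f_r * t_s + t_s / clutter$drift_period_s) +
                        runif(1, 0, 2 * pi))
      }
      # orthonormalize so the clutter has `rank` well-separated singular
      # values, then scale every mode to the target RMS
      U <- qr.Q(qr(U)) * sqrt(nz * nx)
      A <- qr.Q(qr(t(A)))
      A <- t(A) * sqrt(nf) * target_rms / sqrt(clutter$rank)
      chunk <- 2000L
      for (s0 in seq(1L, nf, by = chunk)) {
        s1 <- min(nf, s0 + chunk - 1L)
        idx <- s0:s1
        out[, , idx] <- out[, , idx] +
          array(U %*% A[, idx, drop = FALSE], c(nz, nx, length(idx)))
      }
    }
    if (clutter$noise_sigma > 0) {
      chunk <- 2000L
      for (s0 in seq(1L, nf, by = chunk)) {
        s1 <- min(nf, s0 + chunk - 1L)
        nvals <- nz * nx * (s1 - s0 + 1L)
        out[, , s0:s1] <- out[, , s0:s1] +
          array(rnorm(nvals, 0, clutter$noise_sigma),
                c(nz, nx, s1 - s0 + 1L))
      }
    }
  })
  frame_stack(out, grid, acq$frame_rate_hz, provenance = "raw")
}
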