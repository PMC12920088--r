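# shared fixtures: small deterministic scenes and ground-truth constructors

# a ground_truth object holding explicitly specified bubble-frame positions
manual_ground_truth <- function(frames, x_um, z_um, amplitude = 1,
                                track_id = seq_along(frames),
                                vx = 0, vz = 0, speed = 0,
                                acq = acquisition_config(),
                                duration_s = (max(frames) + 1) / acq$frame_rate_hz) {
  structure(list(
    detections = tibble::tibble(
      frame = as.integer(frames), t_s = frames / acq$frame_rate_hz,
      track_id = as.integer(track_id), segment_id = 1L,
      x_um = x_um, z_um = z_um, vx_mm_s = vx, vz_mm_s = vz,
      speed_mm_s = speed, amplitude = amplitude),
    entries = tibble::tibble(segment_id = 1L,
                             track_id = unique(as.integer(track_id)),
                             t_entry_s = 0),
    tree = NULL, protocol = stimulus_protocol(),
    phenotype = phenotype_params(), acq = acq,
    duration_s = duration_s, seed = 0L), class = "ground_truth")
}

# single straight vessel scene helpers
single_vessel_layout <- function(diameter_um = 28, speed_mm_s = 10,
                                 rate_mb_s = 6, tilt_sd_deg = 3) {
  scene_layout(n_arterioles = 1L, n_venules = 0L, n_act_branches = 0L,
               arteriole_diameter_um = diameter_um,
               arteriole_speed_mm_s = speed_mm_s,
               arteriole_rate_mb_s = rate_mb_s, tilt_sd_deg = tilt_sd_deg)
}

# analysis configuration used for synthetic desk scenes (see vignette):
# SVD cut matched to the known clutter rank, amplitude gate 6 robust sigmas,
# linking gate 30 mm/s for scenes whose fastest class is 10 mm/s,
# 9-frame trajectory smoothing
scene_localize <- function(stack, acq, ...) {
  localize_stack(stack, acq, svd_cut = 5, min_amplitude_snr = 6, ...)
}
scene_link <- function(det, acq, ...) {
  link_tracks(det, acq$frame_rate_hz, max_speed_mm_s = 30,
              smooth_window = 9, ...)
}

# a track_set built from the true bubble identities (perfect localization
# and tracking), for map-level oracles
gt_track_set <- function(gt) {
  det <- gt$detections[, c("frame", "x_um", "z_um", "amplitude", "track_id")]
  names(det)[4] <- "backscatter"
  det <- dplyr::arrange(det, track_id, frame)
  steps <- fulmr:::track_steps(det, gt$acq$frame_rate_hz)
  structure(list(detections = det, steps = steps,
                 counts = list(total = nrow(det), linked = nrow(det),
                               discarded_short = 0L),
                 frame_rate = gt$acq$frame_rate_hz,
                 max_speed_mm_s = Inf, min_track_len = 1L),
            class = "track_set")
}
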