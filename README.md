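# fulmr

Transcranial **functional ultrasound localization microscopy (fULM)**
analysis for R: from ultrafast compound frame stacks to super-resolved
microvascular maps and stimulus-evoked activation read-outs, with a
ground-truthed synthetic scene generator for validation.

Ultrasound localization microscopy tracks individual intravascular
microbubbles across frames acquired at hundreds of Hz. Because each bubble
is a point scatterer, its echo can be localized far below the diffraction
limit; accumulating thousands of trajectories maps cortical microvessels at
micrometre scale and, when synchronized to a sensory-stimulation protocol,
resolves functional hyperaemia down to single penetrating arterioles and
the arteriole–capillary transition (ACT) zone below ~400 µm of cortical
depth. The package implements the full chain:

1. **Clutter filtering** — per-block (200 frames) SVD of the space×time
   Casorati matrix, discarding the largest components (tissue signal).
2. **Localization** — 6× Lanczos interpolation, zero-normalized
   cross-correlation with a Gaussian point-spread template (threshold 0.7),
   non-maximum suppression, 2D quadratic subpixel refinement, and
   backscatter amplitude registration.
3. **Tracking** — optimal bipartite frame-to-frame assignment with a
   100 mm/s speed gate and a 5-frame minimum track length; per-step
   velocity vectors with `v_z > 0` pointing down into the cortex.
4. **Maps** — supercover rasterization of tracks onto a 16× fine grid
   (6.875 µm lateral, λ/16 axial): microbubble flow (MBs px⁻¹ s⁻¹),
   velocity, speed and backscatter maps; 2-s dynamic stacks (35 windows
   per 70-s pattern, 875 over 25 patterns); pattern averaging;
   baseline/stimulation splits.
5. **Vessel quantification** — Frangi vesselness segmentation,
   arteriole/venule classification by axial flow sign, depth profiles,
   backscatter-FWHM diameters, and tortuosity (circular standard deviation
   of the velocity-direction angles; `4·area/(π·major_axis²)` roundness for
   cell somata).
6. **fUS** — power Doppler (per-block mean squared magnitude after a
   60-component cut), GLM activation z-maps with a single-gamma HRF,
   ROI ΔCBV curves with early/late amplitudes and the 20–90% rise time.
7. **fULM activation** — per-pixel relative flow-increase maps,
   depth-banded activation signals, and pattern/acquisition quality control
   (stimulus correlation > 0.3, contralateral correlation within ±0.5,
   10% mean-increase rule).
8. **Synthetic scenes** — vascular trees with descending arterioles, ACT
   continuations and ascending venules; Poisson bubble flux modulated by
   the stimulation pattern; phenotype knobs (dilation, slowing, tortuosity,
   blunted/delayed activation); Gaussian-PSF rendering over low-rank
   pulsatile clutter and white noise, all fully seeded.

Detections, tracks, profiles and QC reports are tibbles that compose with
dplyr; fitted results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` graphics.

## Worked example

Simulate a 24-second scene with a 30% ACT slow-down, run the pipeline,
and read the deep-cortex speed profile:

```r
library(fulmr)

lay  <- scene_layout(n_arterioles = 3, n_venules = 0, n_act_branches = 0,
                     arteriole_rate_mb_s = 4, act_rate_mb_s = 2,
                     tilt_sd_deg = 2)
tree <- build_vessel_tree(lay, phenotype_params(speed_factor_act = 0.7),
                          seed = 1100)
acq  <- acquisition_config(duration_s = 24)
gt   <- simulate_tracks(tree, acq = acq, seed = 1101, duration_s = 24)
st   <- render_frames(gt, scene_grid(lay),
                      clutter_params(rank = 5, noise_sigma = 0.1),
                      seed = 1102)

det  <- localize_stack(st, acq, svd_cut = 5, min_amplitude_snr = 6)
trk  <- link_tracks(det, acq$frame_rate_hz, max_speed_mm_s = 30,
                    smooth_window = 9)
maps <- accumulate_maps(trk, scene_grid(lay), c(0, 24))
trk
#> <track_set> 998 tracks, 29690 detections (6750 discarded), 500 Hz

segs <- segment_vessels(maps, min_major_axis_um = 500)
segs[[1]]
#> <vessel_segment #1> arteriole, length 1923 um, depth 318-2236 um
prof <- depth_profile(maps, segs[[1]])
mean(prof$speed_mm_s[prof$depth_um > 500 & prof$speed_mm_s > 0])
#> [1] 2.68
```

The deep-band reading (~2.7 mm/s) recovers the injected slowed ACT flow
(0.7 × 4 mm/s); the same scenes without the phenotype read ~3.7 mm/s.
`autoplot(maps)` renders the square-root flow map; `plot_tracks(trk)` the
raw trajectories.

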