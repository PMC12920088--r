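---
title: "Functional ultrasound localization microscopy with fulmr: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional ultrasound localization microscopy with fulmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fulmr)
```

## The measurement problem

Ultrasound localization microscopy (ULM) breaks the diffraction limit of
vascular imaging by tracking individual intravascular microbubbles across
ultrafast compound frames. Each bubble is a point scatterer: its echo can be
localized far more precisely than the imaging wavelength, and accumulating
thousands of bubble trajectories paints the microvascular tree at a
micrometre scale. Synchronizing that accumulation with a sensory-stimulation
protocol ("functional ULM", fULM) resolves activity-evoked changes of
microbubble flux down to single penetrating arterioles and the
arteriole–capillary transition (ACT) zone — the first capillary branches
below roughly 400 µm of cortical depth, where mural-cell dysfunction first
manifests in small-vessel disease models. `fulmr` implements that analysis
chain end to end, together with the companion functional ultrasound (fUS)
power-Doppler analysis of the cerebral blood volume (CBV) response, and a
ground-truthed synthetic scene generator used to validate every stage.

## Acquisition model and conventions

The acquisition emulated throughout is a 15 MHz linear probe (110 µm element
pitch) firing groups of 11 tilted plane waves at a 5.5 kHz pulse repetition
frequency, compounded into frames at 500 Hz (`acquisition_config()`).
Whisker stimulation follows repeated patterns of 30 s rest, 30 s
stimulation at 2 Hz and 10 s rest, 25 times (`stimulus_protocol()`).

Geometry (`grid_spec()`): `z = 0` at the cortical surface, z increasing
with depth, so descending arteriolar flow has `v_z > 0` and ascending
venular flow `v_z < 0`. Pixels are half-open intervals
`[k*pitch, (k+1)*pitch)`, indices are 0-based, positions are continuous
micrometres rasterized by `floor(pos / pitch)`. Three grids coexist:

* the native compound grid (110 µm lateral, one wavelength ≈ 102.7 µm
  axial);
* the localization grid, 6× finer (Lanczos interpolation);
* the output grid, 16× finer — exactly 6.875 µm lateral, λ/16 ≈ 6.42 µm
  axial (reported rounded to 6.5 µm elsewhere; the exact λ/16 is stored).

The axial fine pitch follows from the assumed 1540 m/s sound speed; the
printed value 6.5 µm corresponds to a slightly different assumed sound
speed, so we store the exact λ/16 and treat the printed number as a
display rounding.

## The synthetic scene generator

`build_vessel_tree()` lays out a desk-scale cortical field (3 × 3 mm by
default): penetrating arterioles descend from near the surface, continue
below the 400 µm ACT threshold as slower ACT-class segments with short
oblique offshoots, and ascending venules return flow to the surface.
Defaults are the study's printed values where stated (28 µm arteriolar
diameter, 400 µm ACT threshold, 30/30/10 s × 25 stimulation) and field
realism elsewhere: 10 mm/s arteriolar, 4 mm/s ACT and 5 mm/s venular mean
speeds; per-segment baseline bubble rates chosen so the desk field carries
the same spatial detection density as typical in vivo practice (tens of
detections per frame over a ~14 × 9 mm field scales to roughly 5–7 per
frame here). Penetrating vessels receive a random tilt (σ = 6°) and
bubbles a 10% log-normal speed spread — real features whose absence would
also make the synthetic movie unrealistically low-rank in space–time (see
below).

Phenotype knobs (`phenotype_params()`) inject the contrasts the analysis
is meant to recover: diameter dilation, arteriole/ACT flow slowing,
sinusoidal centerline tortuosity, and a stimulus-evoked flux gain in one
arteriolar subtree with configurable onset delay, linear rise (default
2 s) and optional overshoot. `simulate_tracks()` draws bubble entries as
an inhomogeneous Poisson process (thinning), advances each bubble along
the centerline at its own speed with a constant lateral offset drawn
uniformly inside the lumen, and records the exact per-frame ground truth.
`render_frames()` adds the acquisition physics: a Gaussian point-spread
function, low-rank tissue clutter, and white noise.

Three generator choices deserve explanation:

* **PSF width.** The default Gaussian σ is FWHM = 1.8 λ (σ ≈ 79 µm), an
  f/1.8 transcranial aperture. Narrower spots are undersampled on the
  one-wavelength native pitch: at σ = λ/2 the reconstruction aliases and
  localized positions are displaced by up to ~15 µm; even at σ = 65 µm a
  periodic "grid-locking" bias of ~5 µm remains, which visibly distorts
  the lateral mark distribution inside a 30 µm lumen. At the default
  width the locking bias is below 2 µm while localization precision is
  essentially unchanged (the information per echo depends only weakly on
  spot size at fixed echo energy).
* **Clutter.** Tissue clutter is `rank` (default 5) smooth orthonormal
  spatial fields with temporal envelopes mixing a quasi-static drift and
  mouse-cardiac harmonics (10 Hz fundamental — a 600 bpm heart — spaced
  4 Hz). The distinct frequencies matter: slowly drifting envelopes are
  nearly collinear within a 0.4 s processing block, which would make the
  clutter effectively rank-3 and push genuine bubble energy into any
  fixed SVD cut. The amplitude sits 30 dB above the median bubble echo.
* **Scale and rank.** A desk-scale scene is intrinsically closer to
  low-rank than an in vivo acquisition: a slow bubble crossing its own
  PSF in ~10 frames contributes only a handful of independent space–time
  components, and a few parallel vessels share most of theirs. In vivo,
  thousands of bubbles and full-field tissue motion spread energy across
  all available singular components, so removing 20 of 200 costs little
  bubble signal. This is the single most important difference between
  what passing tests here show and what holds on real data, and it drives
  the analysis configuration below.

## Pipeline stages and the parameters that matter

**Clutter filtering** (`svd_filter()`): each 200-frame block is unfolded
to its space × time Casorati matrix and the largest `n_remove` singular
components are zeroed. "Eigenvalues" and "singular values" of the block
are treated as the same operation on that matrix. The package defaults
carry the protocol's empirical cuts — 20 for ULM, 60 for power Doppler.
For synthetic desk scenes the tissue subspace dimension is *known* (the
clutter rank), and a rank-matched cut (5) is the principled choice: the
empirical in vivo cuts would remove most of the (nearly low-rank, see
above) synthetic bubble signal along with the clutter. Tests and the
acceptance script therefore process synthetic scenes with the
rank-matched cut while the package defaults remain the protocol values.

**Localization** (`localize_stack()`): frames are Lanczos-interpolated
(a = 3, 6×), correlated with a unit Gaussian template (zero-normalized
cross-correlation over ±3σ, so the score is invariant to local brightness
offsets), 8-neighbour local maxima above the 0.7 correlation threshold
are kept, maxima closer than one PSF FWHM are reduced to the most intense
one, and a 2D quadratic fit to the 3×3 correlation neighbourhood yields
the subpixel position (offsets clamped to ±0.5 px; non-concave fits fall
back to the integer peak and are flagged). Because normalized correlation
is blind to amplitude, smooth low-amplitude noise can exceed 0.7; an
amplitude gate (default 4, desk scenes 6, robust noise sigmas of the
filtered block) implements the protocol's "most intense maxima" reading
and vanishes on noiseless data. Two further gates target artifacts the
clutter filter itself creates. A sidelobe-rejection pass removes weaker
peaks within 2.5 FWHM of a stronger one unless they reach 40% of its
amplitude: the rectified (|·|) ringing around each echo otherwise
re-detects as satellite bubbles. And a relative amplitude gate (40% of
the block's 95th-percentile detection amplitude) removes "ghosts": the
filter subtracts each bubble's time-averaged ribbon, leaving a rectified
residue along the whole vessel that re-detects as slowly drifting tracks
at 20–40% of a genuine echo. Genuine microbubble echoes are tightly
distributed (log-normal, σ = 0.25), so the relative gate costs ~2% of
real detections; it is disabled for clutter-free data. The measured
localization root-mean-square error at 20 dB echo-to-noise is ~14 µm
(0.13 native pixels) — and a maximum-likelihood Gaussian fit on the raw
frames achieves the same, i.e. the quadratic ZNCC fit operates at the
information floor of this acquisition.

**Tracking** (`link_tracks()`): optimal frame-to-frame bipartite
assignment (Jonker–Volgenant-style, with birth/death costs at the gating
radius), gated at 100 mm/s by default (the protocol value; desk scenes
whose fastest class is 10 mm/s use 30 mm/s, the same "2–3× the expected
maximum displacement" rule a practitioner applies), no gap closing, and a
5-detection minimum track length. Per-step velocities are successive
position differences; because a 500 Hz interframe displacement (6–20 µm)
is comparable to the localization noise, positions are first smoothed
with a symmetric shrinking running mean (default 5 frames; desk-scene
analyses use 9). The smoothing is exact for constant-velocity motion, so
it does not bias clean kinematics.

**Maps** (`accumulate_maps()`): every fine-grid pixel crossed by a step
receives one presence mark (supercover rasterization); flow is marks per
second, speed the plain mark mean, backscatter the mean registered echo
amplitude. Velocity components are averaged with weights 1/`step_px`:
a fixed pixel is touched by long steps more often than short ones, and
without the inverse-length weight that length-biased sampling measurably
dilutes the per-pixel mean velocity. Both the scalar-mean speed and the
vector-mean components are stored; `depth_profile()` reads the
vector-mean magnitude at the flow peak of each orthogonal line because,
within a single vessel pixel, flow direction is constant and the vector
mean is unbiased under localization noise while the mean of noisy speed
magnitudes is Rician-inflated.

**Vessel quantification** (`segment_vessels()` and friends): vesselness
(Frangi, scales 1–8 fine px, β = 0.5, structure constant = half the
maximal second-order structure per scale) on sqrt(flow) × speed
normalized to its 99th percentile; Otsu binarization; morphological
closing (7 px disc) to bridge the sub-pixel gaps sparse sampling leaves
along centerlines; components shorter than 500 µm along the major axis
dropped; arteriole/venule classification by the sign of the flow-weighted
mean `v_z`. Diameters are full widths at half maximum of backscatter
profiles orthogonal to the vessel, averaged over five parallel lines
10 µm apart (single-pixel mean amplitudes fluctuate with per-bubble echo
strength), minus one fine pitch of rasterization widening (a lumen
rasterized into cells and read between cell centres gains exactly one
cell of FWHM). Tortuosity is the circular standard deviation of the
velocity-direction angles of track steps inside the vessel (tracks
shorter than 0.1 mm excluded); the variant statistic — the standard
deviation of scalar products of consecutive unit vectors — is available
via `mode = "scalar"`. Both readings of the tortuosity statistic are
implemented because the two printed descriptions differ; the angular
form is the default.

**fUS** (`power_doppler()`, `glm_activation()`, `roi_response()`): power
Doppler is the per-block mean squared magnitude after the 60-component
cut; activation is pixelwise ordinary least squares of the linearly
detrended series on the stimulus boxcar convolved with a single-gamma
haemodynamic response function (peak 1.5 s — rodent HRFs are much faster
than human ones; shape 3, unit area), with the t statistic mapped to z.
The CBV response uses a 1.4 mm circular ROI on the peak z, normalizes
each pattern to its own rest window, and reports early (36–44 s) and late
(44–60 s) amplitudes plus the 20–90% rise time with linear interpolation
between samples (a pure ramp of duration d yields exactly 0.7 d). The
early/late windows are protocol-relative parameters; the printed values
apply to the 30/30 variant.

**fULM activation** (`activation_map()`, `activation_signal()`,
`pattern_qc()`): baseline (0–30 s) and stimulation (30–60 s) subsets of
the marks give per-pixel relative flow increases, defined only where
baseline flow is positive (never infinite). Depth-banded activation
signals split arteriolar masks at 400 µm. Pattern quality control keeps a
pattern only if its ROI signal correlates with the stimulus boxcar above
0.3, the contralateral correlation stays within ±0.5, and — automating
the manual stable-injection screen — the coefficient of variation of the
whole-image count stays below 0.3; an acquisition is kept only if the
pattern-averaged increase reaches 10%.

## Validation scenes and what they show

The test-suite and the acceptance script rebuild every quantity from
scratch on synthetic scenes sized for a single CPU (each recovery scene
is 16–24 s of 500 Hz acquisition over a 3 × 3 mm field; the activation
scene uses a shortened 10/10/4 s pattern, eight repeats, over a 3 × 1.6 mm
field — problem sizes chosen so the full suite completes in tens of
minutes while each estimate still rests on hundreds of bubble transits):

* **ACT slowing**: control vs `speed_factor_act = 0.7` scenes
  (three well-separated arterioles, no venules, so the experiment
  isolates speed recovery from segmentation confounds), deep-band
  (500–2200 µm) profile speeds. Recovered reduction across seeds:
  ~26–30% for the injected 30%.
* **Dilation**: single-vessel scenes at 28 vs 36.4 µm, backscatter FWHM
  medians over ~30 depths, at a bright-bubble 34 dB echo-to-noise —
  resolving a 28 µm lumen requires localization blur below the vessel
  radius, which 20 dB echoes cannot deliver at this frame rate.
* **Activation**: `activation_gain = 0.5` in a junction-free activated
  subtree (bubble crowding at branch points merges detections and its
  flux-squared scaling would otherwise bias the recovered gain; the
  effect is documented here as a known limitation rather than silently
  folded into the scene). The recovered map gain is compared against the
  ramp-adjusted injected value within the Poisson error of the realized
  transits — the effective sample size of any single-realization flux
  measurement is the number of bubble *transits*, not marks, which is
  what dominates the quoted uncertainty.
* **Tracking**: recall/precision against ground truth on sparse
  clutter-free bright-bubble scenes (~1 bubble per several gating radii,
  rates halved so physically unresolvable co-transiting pairs — two
  bubbles within one PSF FWHM for their whole transit — are rare); this
  criterion isolates the linker, and recall is evaluated inside the
  detector's border margin.
* **Tortuosity**: simulated tracks along sinusoidal centerlines against
  the arc-length-weighted circular standard deviation of the analytic
  tangent angles.
* **fUS**: constructed power-Doppler series (ramp responses, null noise
  fields) — rise time exactly 0.7 × ramp duration; null z-map
  false-positive rate at |z| > 1.96 within binomial error of 5%.

## Numerical choices and degenerate inputs

Truncated Lanczos kernels are renormalized to unit sum (flat fields stay
flat; original nodes are preserved exactly). Ties in local maxima are
broken toward the lexicographically earlier pixel; assignment ties by
earlier detection index. Trailing partial blocks are dropped with a
warning; a stack shorter than one block is an error. An SVD cut at or
above the Casorati rank bound returns an all-zero block. Constant pixel
series get z = 0 in the GLM. Zero-variance QC signals are rejected with
an explicit reason. Diameter profiles that are empty, flat, or multi-lobed
are flagged and carry no value. Pixels with zero baseline flow are masked
(NA) in activation maps, never infinite.

## Known limitations

* The generator collapses elevation: bubbles never leave the imaging
  plane, and out-of-plane amplitude modulation is not modelled beyond the
  per-bubble log-normal echo spread.
* Desk-scale scenes are near-low-rank in space–time; the in vivo SVD cuts
  (20/60) are therefore *not* appropriate for them, and conversely the
  rank-matched cut used here has no in vivo analogue. The module
  surfaces are identical; only the parameter differs.
* Scalar per-step speeds at 500 Hz are Rician-biased whenever the
  interframe displacement is comparable to the localization noise;
  trajectory smoothing and vector-mean profile readings mitigate but do
  not remove this, and the recovered ACT reduction is accordingly
  compressed by a few percentage points.
* Detection merging where vessels crowd (branch junctions, parallel
  vessels within one PSF width) is flux-dependent and slightly
  compresses recovered activation gains at desk scale.
* No aberration, skull attenuation, or motion beyond the low-rank clutter
  model; no gap closing in tracking; no multi-PSF or learned
  localization.
```
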