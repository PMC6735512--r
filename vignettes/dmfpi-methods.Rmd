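---
title: "Respiratory-gated dual-phase perfusion imaging: models and design choices"
author: "dmfpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-gated dual-phase perfusion imaging: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfpi)
```

## The problem

Dynamic contrast-enhanced ultrasound (DCEUS) quantifies tissue perfusion by
recording a cine loop while a microbubble bolus washes through the field of
view, reducing each region to a time-intensity curve (TIC) and estimating
hemodynamic parameters from it. Under free breathing the liver moves through
the fixed 2-D imaging plane: the anatomy imaged at end-of-inspiration (EOI)
is not the anatomy imaged at end-of-expiration (EOE). TICs extracted without
motion handling mix the kinetics of different structures, and parametric
perfusion maps built from them are distorted and noisy.

This package implements a fully automatic dual-phase answer: extract the
breathing kinetics from the loop itself by principal component analysis
(PCA), find the two extreme breathing phases from the derivative of that
curve, keep only the frames at each extreme phase, and build separate
parameter maps for the two phases. Nothing is registered or warped; gating
simply selects self-consistent anatomy.

## Respiratory kinetics by PCA

The loop of `T` frames of `M x N` pixels is flattened to a `T x (M*N)`
matrix whose columns are per-pixel raw TICs (`flatten_sequence()`), each
column is centered by its temporal mean, and the matrix is decomposed into
orthonormal temporal components with spatial weighting vectors
(`pca_decompose()`). The decomposition is the eigendecomposition of the
temporal covariance; numerically it is carried out as an SVD of the centered
matrix for small inputs and as an eigendecomposition of the `T x T` Gram
matrix for large ones — mathematically identical, and the test suite checks
both routes against each other. A deterministic sign convention (each
component's largest-magnitude element is positive) removes eigenvector sign
flips across platforms.

The global bolus kinetics dominates the first component; periodic breathing
motion concentrates in the second (`extract_respiratory_curve()`, default
`resp_component = 2`). Four components are retained by default (`p = 4`):
the third and fourth carry breathing harmonics generated by structures
moving through the plane, and later components are noise. Because the
second-component assumption can fail on unusual data, the extractor warns
when the chosen component has no concentrated spectral peak (its
segment-averaged periodogram maximum falls below 5x the median power —
segment averaging is used here because single-periodogram noise bins have
heavy tails that would defeat a peak test), and the component index is
configurable.

The curve's dominant frequency is the maximum non-DC periodogram bin
refined by parabolic interpolation (`estimate_dominant_frequency()`);
on the bundled phantom protocol it recovers the simulated 0.27 Hz breathing
rate to within half a bin.

## Dual-phase detection and gating

The raw second component is smoothed with a zero-phase moving average
(`smooth_curve()`); the default window, `0.25 * frame_rate / f0` rounded
odd (with `f0` the dominant frequency), passes the breathing fundamental
while suppressing frame noise. Detection (`detect_phases()`) takes the
first difference of the smoothed curve and reads its zero crossings:
a + to - sign change is a local maximum, - to + a local minimum, runs of
exact zeros collapse to their midpoint. Extrema closer than
`min_separation` frames (default half a breathing period) to a stronger
same-class extremum are pruned, and strict EOI/EOE alternation is enforced
by keeping the more extreme of consecutive same-class detections.

Before detection the pipeline applies a narrowband refinement
(`bandpass_curve()`): a zero-phase second-order Butterworth band-pass over
0.6-1.6x the dominant frequency. The extracted component is not a clean
sinusoid — breathing harmonics and bolus-envelope leakage distort its
waveform and shift raw extrema by several frames — and restricting to a
band around the fundamental leaves extremum timing to the breathing cycle
alone. Detections within half a breathing period of either end of the
series are discarded (`exclude_boundary`): their flanks are truncated and
zero-phase filtering leaves edge transients there.

Two conventions here are genuinely open and are resolved as follows:

* **Smoothing before differencing.** The derivative is taken on the
  smoothed curve, not the raw one; differencing amplifies exactly the
  noise the smoother removes.
* **Which extremum is EOI.** An eigenvector's sign is arbitrary, so curve
  maxima cannot be physically identified with inspiration. Maxima map to
  EOI by default with a `swap_phases` switch; on simulated data, where the
  true extreme-phase frames are known, the pipeline resolves the labeling
  against them (the ambiguity is a pure relabeling of the two classes).

Gating (`gate_sequence()`) then selects exactly one frame per detected
extremum, keeping original timestamps — about one sample per breathing
cycle, deliberately without any tolerance-window averaging around the
extremum.

## TICs and denoising

TICs are extracted on a non-overlapping 3x3-pixel grid
(`extract_tic_grid()`) and on user rectangles (`extract_tic_roi()`), as
plain arithmetic means per frame. Gated TICs keep their true nonuniform
timestamps; resampling ~1 sample/cycle data onto a uniform grid would
fabricate observations.

Denoising uses a dual-weighted moving average (`dwma_filter()`): two
cascaded passes of a centered triangular-weighted moving average
(weights `1, 2, ..., ceiling(w/2), ..., 2, 1`, normalized), edges handled
by truncating the window and renormalizing. The cascade interpretation of
"dual-weighted" is a declared design choice, isolated in one operation so
it can be swapped. The default window is 5 samples for full-rate TICs. For
gated TICs the same *sample* count spans a far longer *time* (one breath
per sample) and visibly biases the kinetics — a 5-sample window squashed
gated peak values by ~19% and stretched wash-in times by ~45% at the
protocol's breathing rate — so the pipeline exposes a separate
`dwma_window_gated` (default 3 samples); the filter bandwidth, not the
sample count, is what matters physically.

## Perfusion parameters

`estimate_perfusion_params()` uses threshold-crossing conventions
(10% of peak by default, configurable):
baseline = mean of pre-arrival samples (resolved by a two-pass fixed
point starting from the first sample); `PV` = max - baseline; `t_peak` =
earliest argmax; `t_arrival` and the washout point are the first crossings
of `baseline + 0.1 * PV`, refined to sub-sample precision by linear
interpolation between the bracketing samples (exact whenever the crossing
falls on a sample; essential for gated TICs, whose raw time quantization
is a whole breathing cycle); `WIT = t_peak - t_arrival`;
`WOT` = washout - peak, truncated at acquisition end with
`washout_complete = FALSE` when the falling phase is only partly recorded;
`AUC` = trapezoidal integral of the baseline-subtracted curve from arrival
to washout; `WIR = PV/WIT`, `WOR = PV/WOT` (ratio form; a maximum-slope
variant was considered and rejected as far noisier at gated sampling
rates). Flat or degenerate TICs yield a `defined = FALSE` flag rather than
NaNs.

Maps are built at grid resolution (`build_parameter_maps()`), restricted to
the perfusion region (`perfusion_region()`: cells whose PV reaches 20% of
the map's 99th-percentile PV — with noise every cell is nominally
"defined", and evaluation is meant to cover perfused tissue, not
background), normalized to a shared dynamic range across the conditions
being compared (`normalize_shared_range()`; the pipeline uses the pooled
1st-99th percentile range so a handful of corrupted outlier cells cannot
compress everyone else's encoding), quantized to 256 levels, and colour
coded through a fixed blue-cyan-green-yellow-red lookup table shipped as a
CSV asset so encodings are bit-reproducible (`encode_rgb()`, `dmfpi_lut()`).

## Evaluation metrics

* `scr()` — signal-to-clutter ratio: `10 log10` of integrated periodogram
  power below a cut-off `f_c` (DC excluded) over power above it, capped at
  ±120 dB. Default `f_c` = 0.15 Hz: below the 0.27 Hz breathing rate,
  above the bolus-kinetics bandwidth. Gated TICs are evaluated at their
  mean sampling rate; since their Nyquist rate (~0.135 Hz) falls below the
  default cut-off, the pipeline clamps the effective cut-off to 45% of the
  TIC's own Nyquist rate.
* `tic_mse()` — curves linearly resampled onto their overlapping span at
  the coarser rate, mean squared difference.
* `value_density()`, `fpi_mse()`, `fpi_correlation()` — value-probability
  densities of two maps over shared bin edges; their mean squared
  difference (scaled by 1e6, a fixed documented constant) and Pearson
  correlation. The pipeline uses 32 bins: the operations default to 256
  (matching the encoding levels), but a histogram of a few hundred region
  cells spread over 256 bins is dominated by sampling noise, and ~sqrt(n)
  bins is the standard density-estimation compromise.
* `mnc()` — mean noise coefficient: per-channel coefficient of variation
  (population sd / mean, in percent) over the valid cells of the colour
  map, averaged over the three channels; a constant channel contributes
  zero. The pipeline computes it on a monotone gray coding
  (r = g = b = level) over each map's own robust range: MNC is a per-map
  quantity, and under a non-monotone display colormap a channel can have
  near-zero mean purely because of where the values sit on the colour
  scale, which makes the coefficient meaningless.

## The phantom simulator

No public DCEUS acquisitions accompany the protocol, so validation uses a
synthetic flow phantom (`simulate_dceus()`) that emulates the in vitro
design: a vessel cross-section (5 mm lumen, 1.5 mm wall, 0.1 mm/pixel,
128 x 128 frames) imaged at 21.3 Hz for 120 s while a log-normal bolus
washes through and the section deforms periodically at 0.27 Hz. Its
components, and what they emulate:

* **Out-of-plane motion in 2-D.** A physical rotary stage sweeps the
  imaging plane through the tube; what the image sees is the cross-section
  translating and rescaling. Motion state is `sin(2*pi*0.27*t)`; the
  vessel's axes scale by `1 + 0.3 * m(t)` and its center translates
  proportionally (`resp_amplitude = 0.3`).
* **Laminar flow profile.** Tube flow is not plug flow: the bolus at
  normalized radius `rho` arrives `5 * rho^2` s later, its amplitude falls
  by up to 50% at the wall, and its log-scale location grows by
  `1.0 * rho^2` (near-wall streamlines are slower and disperse more,
  stretching wash-in/wash-out about e-fold at the wall; ideal
  Poiseuille flow diverges at the wall, so a truncated quadratic is used).
  The spread this puts into the parameter maps must comfortably exceed the
  time quantization of gated sampling (one sample per breath) for
  dual-phase mapping to be informative, as it is in the physical
  protocol's slowly evolving TICs.
  All six parameters therefore vary smoothly across the lumen, as real
  parametric maps do, and the analytic truth maps follow in closed form
  from the axis parameters (time-stretch `k = exp(0.7 rho^2)`, amplitude
  factor `s = 1 - 0.5 rho^2`: `WIT, WOT ~ k`, `PV, WIR, WOR ~ s/k,
  s/k^2`, `AUC ~ s`).
* **Alternate-phase anatomy.** The defining feature of out-of-plane motion
  is that *different structures* occupy the slice at the other breathing
  phase — neighbouring vessel sections with their own bolus kinetics and a
  non-perfused gallbladder-like structure. Three such structures fade in
  with `max(-m(t), 0)`: a bright late vein, a dark non-perfused disc, and
  a faint early vein. They are what corrupts ungated analysis: an ungated
  TIC interleaves two different vessels' kinetics, so its peak, arrival
  and washout can come from the wrong structure entirely. Their kinetics
  follow the same injection as the main vessel (arrivals a few seconds to
  tens of seconds apart), and the structure that enhances before the main
  vessel is kept faint: a bright structure enhancing while the main
  vessel's motion signature is still weak would dominate the second
  component's carrier during that epoch and invert its extrema — a real
  failure mode of PCA gating that the warning in
  `extract_respiratory_curve()` cannot catch, since the component still
  has a strong respiratory peak.
* **Speckle and thermal noise.** Multiplicative log-normal speckle
  (unit mean, log-sd 0.2) plus additive Gaussian noise (sd 2), clipped at
  zero.
* **Soft edges.** Compartment boundaries blend over a 0.3 mm linear ramp
  (finite beam width). Pixels deeper than half a ramp keep pure
  compartment values, so interior-lumen TICs are exactly the analytic
  bolus; the ramp also concentrates the motion signal at the breathing
  fundamental instead of spraying it across square-wave harmonics.
* **Ground truth.** Motion-frozen static loops at the two extreme states
  (same bolus, independent noise), the analytic motion series with its
  extremum frames, per-pixel analytic parameter maps, and lumen masks.

Bolus defaults (`t_arrival` 10 s, area 12000, `mu` 3.3, `sigma` 0.5,
baseline 5) were chosen so that (a) the wash-in spans several breathing
cycles — the gated sampling rate must resolve the kinetics for dual-phase
analysis to be meaningful, which is also true of the physical protocol's
TICs — and (b) the variance decomposition reproduces the canonical
structure: bolus kinetics first (~48% of variance), breathing second
(~17%, matching the ~20% the protocol reports), harmonics third and
fourth. With weaker enhancement, breathing overtakes the bolus and the
second-component assumption breaks — a real failure mode of the method,
reproducible here by lowering the bolus area.

### What the phantom does not emulate

Real speckle is spatially correlated and band-limited; here it is
per-pixel independent. Breathing is perfectly periodic (the in vitro stage
was mechanical; in vivo breathing drifts in period and amplitude, which
makes gating harder). Attenuation, depth-dependent gain, nonlinear
log-compression of the video signal, transducer geometry and recirculation
of the contrast agent are all absent. Passing the bundled comparisons
therefore shows the scheme's machinery is correct under the stated motion
model; it does not certify performance on clinical loops.

## Numerical and interface choices

* Indices are 1-based throughout (frames, ROI rectangles, phase indices),
  following R convention.
* All randomness flows from a single integer seed; identical configuration
  and seed reproduce every numeric output bit-identically, including the
  written PNG/JSON artifacts.
* Flattening puts pixel `(row, col)` in column `(row-1)*N + col`; the
  round trip through `unflatten_matrix()` is exact.
* TIFF output is 8/16-bit integer (bit-identical round trip); non-integer
  sequences must be quantized by the caller, and the command-line wrapper
  rounds simulated loops to integer video levels before export. Maps go
  to 8-bit PNG; tables to CSV at full double precision; metric reports
  and manifests to JSON.
* The problem sizes exercised by the test suite are the full protocol
  loop (128 x 128 x 2556) for the end-to-end checks and a 56 x 56 x 400
  phantom with the same variance structure for unit tests.

## Known limitations

* Gated TICs carry ~1 sample per breathing cycle; time parameters are
  quantized at that scale before interpolation, and ratio parameters
  (WIR, WOR) inherit the noise of both numerator and denominator. Slow
  kinetics relative to the breathing period are intrinsically favourable.
* The respiratory component index is an assumption (validated here, and
  warned about when violated), not an inference; unusual acquisition modes
  may require `resp_component` or `swap_phases` overrides.
* The EOI/EOE physical labeling cannot be determined from the loop alone;
  on real data it must be fixed by the operator (one glance at the cine at
  a detected extremum suffices).
* Density metrics compare value distributions, not spatial agreement; two
  maps with identical histograms but permuted cells are indistinguishable
  to them. Cellwise comparisons are available by working with the map
  `values` directly.
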