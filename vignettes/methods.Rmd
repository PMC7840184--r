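---
title: "Methods: motion, calcium and transport quantification in tubuliflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion, calcium and transport quantification in tubuliflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tubuliflow)
```

This vignette records the models, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what is
computed, under which assumptions, and what a passing test does and does
not establish.

## 1. The measurement model

A recording is a calibrated set of channels (`f340`/`f380` fura-2
excitation pair, `gcamp`, `brightfield`, `background`), each an H×W×T
array with frame interval `dt` (s) and `pixel_size` (µm/px). All times are
`frame_index × dt` with t = 0 at the first frame; stimulus onsets live on
this clock. All physical outputs derive only from `dt` and `pixel_size` —
there are no hidden unit constants.

### Displacement fields and flow metrics

Contraction is measured through a dense displacement field: at frame i,
`v_(p,q)` is the vector such that the reference frame at pixel (p,q)
matches frame i at (p,q) + v. With reference mode `to_t0` the reference is
the first frame (the convention used for acute-slice contraction
analysis); with `consecutive` it is the previous frame (used for luminal
transport, where motion is frame-to-frame particle movement rather than
cumulative deformation). Flow strength `s_i` is the ROI-mean vector norm;
flow change `c_i` differences the moving-average-smoothed `s` series
(window default 5 frames, always odd, shrinking at the edges; window 1 is
a bitwise no-op, which makes the telescoping identity Σc = s_k − s_0
exact). AUCs are trapezoidal integrals over a post-onset window (default
60 s) with an equal-length pre-onset basal companion.

**Signed vs rectified AUC.** The flow-change series integrates to
approximately zero over any window containing both the contraction and its
relaxation, so the package integrates |c| by default (option `rectify =
FALSE` restores the signed integral). The rectified integral is what makes
post-stimulus AUC increase monotonically with contraction amplitude, the
property the transport analysis depends on.

### The flow estimator

Upstream implementations of this analysis relied on published variational
optical-flow code; this package specifies an accuracy contract instead of
an algorithm, and its default estimator is a Gaussian-windowed least-squares
(Lucas–Kanade-type) scheme with forward-additive warping: per iteration,
spatial/temporal gradients of the 1-px-presmoothed images are aggregated
under a Gaussian window (σ = 4 px), the 2×2 normal equations are solved
per pixel with a small relative Tikhonov term, updates are clamped to 1 px
per iteration, and iteration stops when the mean update norm falls below
0.003 px. Two design points deviate from the textbook coarse-to-fine
recipe, both adopted after the pyramid variant failed its own accuracy
contract on this package's phantoms:

- **Global initialization instead of a pyramid.** Coarse pyramid levels of
  small (64 px) frames are dominated by border effects and inject large
  localized errors that fine levels cannot repair. A whole-frame FFT
  cross-correlation translation estimate (Hann-windowed, with parabolic
  subpixel refinement) provides the large-motion initialization instead;
  the clamped iterations then track residual non-rigid motion. Rigid
  shifts up to 5 px are recovered with mean vector error well under
  0.25 px (under 0.5 px at SNR 10), and radial contraction fields up to
  8 px amplitude are tracked with errors of a few percent.
- **Warm starting.** In `to_t0` mode the field at frame i initializes the
  solve at frame i+1; successive fields differ by one frame's motion, so
  convergence typically takes 1–2 iterations.

Vectors within `ceiling(3σ)` px of the border are flagged and excluded
from ROI statistics (dense flow is ill-posed at borders). Consecutive
fields can be composed into t0 reference (`compose_to_t0`) by
v_i(p) = v_(i−1)(p) + u_i(p + v_(i−1)(p)).

Drift correction is deliberately *not* a flow problem: per-frame global
translations (FFT cross-correlation) are fitted against frame index by a
Theil–Sen median-of-slopes regression, and only that constant-velocity
component is removed. The median slope is insensitive to a transient
contraction occupying a minority of frames, which is exactly the property
the correction needs.

### Calcium traces

The fura-2 ratio is the **mean of per-pixel ratios** over the ROI, the
formula this analysis tradition prescribes — not the ratio of ROI means (both
are implemented; the difference is a Jensen-gap that the tests
demonstrate on a 2-pixel example). Pixels with `f380` below 1% of the
channel maximum are excluded and counted rather than divided by. Both
channels are stabilized with a *single* field estimated on their pixelwise
sum, so registration error cannot masquerade as a ratio change.

Reported GCaMP normalizations in this literature are ambiguous about the
denominator, so the package implements both readings — `(F_i − F_b)/F_b`
(`dff0`, the field convention and the default) and `(F_i − F_b)/F_i`
(`dffi`, current-frame denominator) — and records the convention used in
the trace metadata.

The responder criterion (baseline mean + 3 SD exceeded for ≥2 consecutive
frames within a 60 s response window) is this package's own
formalization; published response rates for this preparation come
without a stated threshold. At these defaults the false-positive rate on pure-noise traces
is ≤5% (tested).

### In-vivo preprocessing chain

- **Flicker / bleach**: per-frame histogram matching onto the first frame
  (monotone quantile map; rank order preserved exactly; idempotent).
  Mains ripple at 50 Hz aliases into frame-level multiplicative gain at
  ≤10 Hz frame rates, which is why a frame-wise histogram remedy is
  appropriate and why the phantom's `corrupt()` models flicker as
  per-frame gain rather than within-frame banding.
- **Gaussian filtering**: spatial blur per frame then a purely temporal
  blur (x = 0, y = 0 in the z-pass). ImageJ "radius" is converted as
  σ = radius/2 (a documented, configurable constant — the upstream workflow names a
  plugin, not a kernel); defaults radius 5 px, temporal σ 5 frames.
- **Dye separation**: a single global bleed coefficient α from
  least-squares regression (with intercept) of target on background over
  baseline frames; corrected = target − α·background, floored at 0. α is
  global because single-fluorophore spectral bleed is; the regression
  intercept absorbs uniform offsets so they do not bias α.
- **Transient isolation**: per-pixel running low-percentile baseline
  (default: 10th percentile over a 50-frame centered window) subtracted.
  The upstream macro's internals are unpublished; this implements its
  stated goal and is pinned by property tests (statics → 0, boxcar transients
  keep amplitude within 10%).

### Transport directionality

ROI sections are arc-length bins of a centerline band: each band pixel is
assigned to exactly one section by binning its projection, so sections
tile the band with no gaps or overlaps (tested as a pixel-set partition).
The ascending-stage direction is always an explicit input — stages are
determined visually in the experiment and are not inferrable from
brightfield images. DI uses the supra-basal rectified excess
max(AUC − basal, 0) per side, because basal luminal motion exists before
stimulation and must not contribute to directionality; reversing the
stage direction negates DI exactly. Physical section length is a required
input (the standard layout runs up to ROI ±6, but no canonical section
length exists).

### Kymographs and wave velocity

Polylines are spline-smoothed before normals are computed (hand-drawn
polylines have corner artifacts); arc length is preserved so the output
column axis is µm. Onset per spatial bin is the first crossing of
half-max (linearly interpolated); velocity is the slope of position (µm)
regressed on onset time (s) — that order makes the slope µm/s directly
and the sign the propagation direction. The half-max-onset regression is
this package's formalization of "linear regressions on kymographs"; the
fit is declared invalid for <5 crossing bins, onset spread <2 frames
(synchronous), or r² < 0.5.

### Dose-response and events

Hill fits fix the bottom at 0 (responses are baseline-subtracted
amplitudes; a free-bottom variant is one flag away), normalize to the
response at 100 µM by default, and use multi-start Nelder–Mead over
log-parameters with a Gauss–Newton polish. Enhanced-activity episodes
chain events whose inter-onset gaps are ≤90 s and keep chains with ≥2
events; the chaining reading of "within 90 s" is shift-invariant, unlike
a fixed tiling. Calcium/contraction pairing is greedy by maximal temporal
overlap; unmatched contractions are "passive" (movement without a calcium
signal), unmatched calcium events "silent". Pearson r is primary for
duration correlation (Spearman reported alongside); the claim being
formalized is only that the correlation is positive.

## 2. The synthetic world

The phantoms are the package's evidence base, so their defaults state the
experimental regime rather than a convenient test point: 1 Hz acquisition
(the slice/whole-mount frame rate), a ~40 µm tubule in a 64×64 µm field,
single-exponential rise (2 s) and decay (10 s) transient kinetics, a
calcium transient leading contraction by 1 s, 100 µM / 10 s ATP stimulus
encoding, wave velocities of tens of µm/s over a 500 µm tubule (in-vivo
regime), and tubule lengths within the 200 µm–3.4 mm range such preparations
support. Rendering is analytic with area-weighted (1 px linear ramp)
edges, so subpixel displacements are faithfully representable and the
truth displacement field is exact by construction, not by interpolation.
The GCaMP channel adds only a small dark offset (2 intensity units)
inside the tubule: a large camera offset would attenuate measured ΔF/F
below the configured indicator amplitude, which would conflate generator
bias with extraction error.

What the phantoms deliberately do **not** model: photon-level optics,
biophysical excitation–contraction coupling, tissue scattering,
non-rigid jitter, or stage-dependent tubule anatomy. A green test
establishes that each algorithm recovers the quantity it claims from data
with the stated geometric and statistical structure — not that the
pipeline is robust to every artifact of real recordings.

Scaled-down geometry in tests (48×48 frames, 30–50 frames, 20 s AUC
windows instead of 60 s) keeps the suite inside its time budget; the
60 s default and the full-size defaults are asserted separately as
defaults, and nothing in the algorithms depends on scale.

## 3. Numerical choices and edge cases

- Replicate (edge-clamp) padding everywhere: warps, convolutions, MSE
  windows. The brute-force oracles in the tests reproduce the same
  boundary semantics by independent means.
- Windowed-MSE tie-break: candidate shifts are ordered by (‖d‖, dy, dx)
  and only a strictly smaller error replaces the incumbent, so a static
  stack yields exactly zero motion.
- ROI rasterization: even-odd rule on 0-based pixel centers,
  boundary-inclusive (a center exactly on an edge is inside), verified
  pixel-for-pixel against a brute-force point-in-polygon oracle.
- The TIFF codec is a minimal baseline implementation (little-endian,
  uncompressed, grayscale, single-strip writes, multi-strip reads,
  uint8/uint16/float32) written because no TIFF-capable R package is
  available in the target environment; it is round-trip tested and
  cross-validated against an independent Python reader/writer.
- Histogram matching uses rank ties "first", making the map deterministic
  and idempotent.
- `FlowSeries` requires an odd smoothing window ≥1 and enforces
  `length(c) = length(s) − 1`; degenerate baselines in responder
  classification fall back to an absolute floor; drift estimation
  requires ≥10 frames.

## 4. Known limitations

- The flow estimator's σ = 4 window trades spatial resolution for
  robustness; motion features much smaller than the window are smoothed.
  Fields with pathologically flat texture regions can contain locally
  unreliable vectors (hence the border flagging and ROI averaging).
- `windowed_mse_motion` returns integer-norm displacements by
  construction; sub-pixel motion between consecutive frames is invisible
  to it (use flow norms for slow waves).
- The Hill fit reports a single global optimum from multi-start; it does
  not profile uncertainty.
- No 3-D motion, no per-particle tracking, no automatic stage
  classification, no proprietary microscope formats.
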