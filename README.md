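# tubuliflow

Quantitative analysis of seminiferous-tubule time-lapse imaging: tubule
contractions, peritubular calcium signals, and directional luminal
transport.

## The problem

The wall of each seminiferous tubule is lined by smooth-muscle-like
testicular peritubular cells (TPCs). Their coordinated, ATP-triggered
contractions propel immotile spermatozoa through the tubule lumen toward
the rete testis. Demonstrating this quantitatively requires extracting,
from multi-channel time-lapse microscopy, several linked measurements:

- **Motion**: a dense displacement field `V_i` registering every frame to
  the reference frame `t0`. The contraction magnitude at frame `i` is the
  *flow strength* `s_i = (1/mn) Σ_{p,q} ‖v_{p,q}‖`, the ROI-mean Euclidean
  norm of the displacement vectors; the *flow change* `c_i = s_i − s_{i−1}`
  (after moving-average smoothing of `s`) captures frame-to-frame motion
  events, quantified as the area under the `c_i` curve within 60 s of
  stimulation onset.
- **Calcium**: fura-2 ratio traces (per-frame *mean of per-pixel*
  `f340/f380` ratios over an ROI, after registering both channels with a
  single displacement field estimated on their sum) and GCaMP ΔF/F traces
  normalized to a pre-stimulus baseline.
- **Transport directionality**: the tubule is partitioned into equidistant
  sections ROI 0 (directly stimulated) through ROI ±6; supra-basal motion
  AUC per section, summarized by a directionality index
  `DI = (A⁺ − A⁻)/(A⁺ + A⁻)` over the ascending/descending stage sides.
- **Waves**: tubules are digitally straightened along a polyline, motion
  intensity is averaged over transversal profiles into space×time
  kymographs, and wave velocity is the slope of the regression of position
  on onset time.
- **Dose-response**: Hill fits `r(c) = rmax·c^h/(EC50^h + c^h)` to
  responses normalized to 100 µM ATP, plus enhanced-activity episodes
  (≥2 contractions within 90 s) and calcium/contraction duration
  correlation.

No public recordings exist for this preparation, so the package ships a
synthetic phantom generator (`make_contracting_tubule`, `make_wave_movie`,
`make_transport_movie`, `make_dose_response`, `corrupt`) that renders
movies with exact ground truth for every recoverable quantity — every
analysis stage is verified by ground-truth recovery.

## Worked example

```r
library(tubuliflow)

# a contracting tubule: 64x64 px, 1 um/px, 1 Hz, 4 um contraction at t = 10 s
ph <- make_contracting_tubule(phantom_params(amplitude_um = 4, onset_s = 10,
                                             n_frames = 40, seed = 1))
field <- estimate_displacement(ph$recording, channel = "brightfield")
s <- flow_strength(field, ph$truth$wall_mask)
round(max(s), 2)          # 4.02  -- peak flow strength, px (truth: 3.98)

# stabilize the calcium channel with the estimated field, then extract
gc_stab <- apply_displacement(get_channel(ph$recording, "gcamp"), field)
dff <- extract_dff_trace(gc_stab, ph$truth$wall_mask, baseline_spec(c(0, 8)))
round(max(dff$values), 2) # 0.46  -- peak dF/F (configured: 0.5)

fit <- fit_hill(c(1, 3, 10, 30, 100, 300),
                make_dose_response(ec50 = 10, h = 1, rmax = 1,
                                   concentrations = c(1, 3, 10, 30, 100, 300))$responses,
                normalize_at = NULL)
round(fit$ec50, 4)        # 10    -- EC50 recovered exactly on clean data
```

The peak flow strength (4.02 px) is the ROI-mean displacement magnitude at
the contraction maximum; with 1 µm/px it reads directly as ~4 µm of inward
wall movement, matching the configured amplitude (truth 3.98 px after
kinetic sampling). The ΔF/F peak (0.46) recovers the configured indicator
amplitude of 0.5 to within the interpolation loss of stabilization, and
the Hill fit returns the generating EC50 exactly on clean data.

## Command line

```sh
tubuliflow simulate --kind contraction --out demo --seed 1
tubuliflow register --stack demo/stack.tif --config demo/config.json --out demo
tubuliflow fit-dose-response --csv dose.csv --out results
```

(Also `analyze-slice`, `analyze-whole-mount`, `analyze-invivo`; the script
installs to `<library>/tubuliflow/exec/tubuliflow`.)

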