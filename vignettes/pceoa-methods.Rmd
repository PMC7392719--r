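---
title: "Methods: phase-contrast EOA for bioprosthetic mitral valves, in silico"
author: "pceoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-contrast EOA for bioprosthetic mitral valves, in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pceoa)
```

## The measurement problem

Doppler echocardiography is the first-line tool for assessing bioprosthetic
mitral valve (BMV) function, but in some patients it is technically limited.
Phase-contrast (PC) cardiovascular magnetic resonance offers an alternative:
a PC acquisition perpendicular to the trans-prosthetic inflow jet yields a
per-pixel through-plane velocity map at every cardiac phase. From such a
series one can measure:

* **FFV** — forward flow volume, the time integral of instantaneous flow
  (ROI velocity sum × pixel area) over the beat, in mL;
* **peak velocity** and its **TVI** — the time–velocity integral of the
  per-frame peak jet velocity over the filling period, in cm;
* **PC-EOA** — the effective orifice area, `EOA = FFV / TVI` (cm²), the mean
  diastolic cross-section actually occupied by flow at the plane of maximal
  velocities;
* **AOA** — the planimetric anatomic orifice area, a single-frame geometric
  measurement.

The package implements this pipeline end to end, a continuous-wave (CW)
Doppler analog pipeline (envelope-derived indices plus the continuity-style
`EOA = FFV_reference / TVI_Doppler`), the method-agreement statistics used to
compare them (Pearson r, Bland–Altman bias and limits of agreement,
single-measure ICCs), and a pulsatile flow-loop simulator that provides
ground truth. Everything is driven by an experiment module that reproduces a
24-condition validation grid: normal valves of 27/29/31/33 mm and 27/29 mm
valves with one or two leaflet occluders, each pumped at 70, 90 and
110 mL/beat and 70 bpm.

## Ground truth: pump and valve model

**Waveform.** One cycle of the pump is a single-phase diastolic filling
waveform `Q(t)` (mL/s): zero everywhere except the first
`filling_fraction` of the cycle, with either a half-sine lobe or an
`e_wave` shape (a raised cosine over the first 60 % of the filling window
plus a 0.35-amplitude raised cosine over the last 55 %, overlapping and
summed). The waveform is renormalized so its trapezoidal integral equals the
stroke volume exactly; all downstream volume errors are therefore
attributable to the measurement chain, not the generator. There is no
atrial-contraction (A-wave) component and no regurgitant flow — the modeled
rig has neither.

The pump's filling fraction is not an observable we could copy; it controls
how peaky the jet is at a given stroke volume. We fix the default at 0.75 of
the cycle because, with the default valve parameterization below, it is the
smallest-peak choice that keeps the severe-stenosis envelope peaks at
110 mL/beat inside the clinically reported stenotic range (151–418 cm/s)
while remaining a plausible single-phase filling window for a pulsatile
pump. It is a config option (`pump$filling_fraction`), not an inference
about any particular rig.

**Valve.** A valve configuration is (nominal size, occluder count, anatomic
orifice area AOA, contraction coefficient Cc). Only group-level area
statistics are published for rigs of this kind, so per-valve AOAs are free
parameters chosen to reproduce them: normal AOAs of 2.4/2.7/3.1/3.4 cm² for
27/29/31/33 mm (group mean 2.9 cm²), multiplied by 0.55 for a single
occluder and 0.35 for a double occluder (stenotic group mean ≈ 1.2 cm²).
The effective jet area is `A_eff = Cc × AOA` with Cc defaulting to 0.62 for
normal and 0.85 for stenotic valves: flow contraction spans roughly 0.6–1.0,
and a stenotic orifice under a higher driving gradient uses relatively more
of its anatomic area, so its Cc sits closer to 1. The ground-truth jet
velocity is `v(t) = Q(t) / A_eff` by conservation of volume flow.

## Synthetic PC acquisition

Each frame of a synthesized series is a centred, circular jet on the pixel
grid. The radial velocity profile is a tanh shoulder

$$ s(r) = \tfrac12\left(1 - \tanh\frac{r - r_{mid}}{w}\right), $$

with `(r_mid, w)` solved jointly per valve so that

1. the profile integrates to `A_eff` — the jet carries exactly `Q(t)` when
   its plateau velocity is `v(t)`; and
2. the 10 %-of-max level set sits at the anatomic radius
   `sqrt(AOA / pi)` — so low-threshold planimetry recovers the AOA.

The shoulder between those two radii represents the slow convergence /
partial-volume skirt between the vena contracta and the anatomic orifice
rim: wide for normal valves (strong contraction, Cc ≈ 0.62), thin for
stenotic ones (Cc ≈ 0.85). This is the one place the synthetic world encodes
the AOA > EOA structure, and it is what makes a single-plane series support
both planimetry and flow quantification, as the two thresholds (0.1 anatomic
base vs 0.5 jet core) do clinically. Pixel values are averaged over a 3×3
sub-pixel sampling of the profile (in-plane partial voluming), and the
discrete pattern is rescaled so that its pixel sum times pixel area is
exactly `A_eff` — the discretized jet carries the specified flow.

Acquisition degradations, all configurable via `acquisition_params()`:

| parameter | default | meaning |
|---|---|---|
| `pixel_spacing_mm` | 1.2 × 0.9 | in-plane resolution |
| `slice_thickness_mm` | 4 | through-plane extent (metadata only) |
| `frame_interval_ms` | 48.9 | temporal resolution; frames at mid-frame times |
| `temporal_window_ms` | 48.9 | boxcar time-average per frame (view sharing may exceed the interval) |
| `noise_sd_cm_s` | 3 | per-pixel Gaussian velocity noise |
| `spatial_smooth` | TRUE | 3×3 boxcar per frame (partial voluming / reconstruction) |
| `venc_cm_s` | 400 | aliasing ceiling; wrap modulo 2·VENC only if `aliasing = TRUE` |
| `grid_size` | 64 × 64 | field of view |

The frame value of the jet plateau is the boxcar time-average of `v(t)`
centred on the frame time, which is why a coarse acquisition can only blunt,
never exaggerate, the apparent peak velocity (the maximum of an average is
at most the maximum). VENC wrap-around is implemented but off by default:
clinically the VENC is chosen above the expected jet velocity, and 400 cm/s
clears every default grid condition. The experiment driver divides the noise
SD by √8 to model an 8-average acquisition. Temporal resolution, in-plane
resolution and frame count mirror a clinical segmented PC protocol.

The CW Doppler analog is sampled at ≤ 5 ms: the true velocity trace scaled
by a spectral-broadening factor (default 1.05 — CW envelopes track the upper
edge of the spectral distribution and overread the true maximum by a few
percent, which is also the direction needed for the Doppler-vs-PC
asymmetries discussed below), plus Gaussian noise, clipped at zero, over
`n_beats` identical pump beats whose only variability is noise.

## Analysis pipeline choices

* **Segmentation** (`segment_jet_roi`): reference frame = frame of greatest
  spatial-sum velocity; threshold = fraction of that frame's maximum; mask =
  largest 4-connected supra-threshold component per frame; empty frames
  inherit the reference mask. The contour software used clinically is
  proprietary and unspecified, so this operation *defines* the stand-in.
* **Flow ROI**: the 0.1-threshold mask grown by 4 pixels before flow
  summation. A level-set mask clips the outer half of the smooth jet
  shoulder and loses several percent of flow; growing the contour is the
  in-silico analog of drawing it generously around the jet, and is what
  makes the EOA identity below hold to a fraction of a percent.
* **FFV**: trapezoidal integral of `max(flow, 0)` over the whole cycle. The
  filling phase is the only flow source, so windowing would only discard
  ramp frames; clipped noise outside it contributes negligibly.
* **TVI**: per-frame ROI maximum (a percentile option exists because noise
  inflates maxima), integrated over the filling window: the longest run of
  samples above 5 % of the trace maximum, then traced outward to baseline
  through monotonically decaying positive samples — the way a reader closes
  an envelope tracing. The floor rejects systolic noise; the baseline walk
  keeps the onset/offset ramps.
* **AOA**: pixel count of the 0.1-threshold mask at the peak-flow frame ×
  pixel area, a deliberately lower threshold than the 0.5 jet core: AOA
  measures the anatomic opening, EOA the flow area.
* **Gradients**: simplified Bernoulli `ΔP = 4 v²` (v in m/s), peak from the
  trace maximum and mean as the time average over the filling window.
* **Integration**: trapezoidal rule throughout; no spline resampling. The
  oracle tests bound its error directly.

**The central oracle.** For a noise-free, densely sampled uniform jet the
pipeline satisfies an exact identity: `FFV = ∫Q dt` and
`TVI = ∫Q/A_eff dt`, hence `PC-EOA = FFV/TVI = A_eff = Cc × AOA`. The test
suite checks this to 0.5 % over all 24 grid conditions and both waveform
shapes; it is what makes EOA recovery a parameter-recovery problem rather
than a calibration.

**Error directions.** Under realistic acquisition (48.9 ms frames,
full-frame averaging, noise), PC-TVI sits slightly below the Doppler TVI
(coarse sampling of a concave lobe, window-edge losses) while the broadened
CW envelope sits slightly above truth; since EOA divides FFV by TVI, PC-EOA
lands slightly above Doppler EOA while both straddle the true `Cc × AOA`.
These are the directions reported for the physical rig, and the acceptance
suite asserts them on every grid condition.

## Agreement statistics

Differences are consistently oriented second method − first method (the
reports label it). Bland–Altman limits use the classic 1.96 × SD(diff)
(n−1 denominator), no small-sample t correction. ICCs are the Shrout–Fleiss
single-measure forms computed from the ANOVA mean squares — one-way random
`(MSB − MSW)/(MSB + (k−1)MSW)` and two-way random
`(MSR − MSE)/(MSR + (k−1)MSE + k(MSC − MSE)/n)` — with negative estimates
reported as-is rather than clipped; the tests verify both against
`stats::aov` mean squares to 1e-10. No confidence intervals on r or ICC are
produced, and there is no repeated-measures Bland–Altman correction.

## Problem sizes and reproducibility

The default grid is 24 conditions × (one PC series of ~17 frames of 64×64
pixels + one 5-beat CW trace at 2 ms); it runs in a few seconds on one CPU.
The dense noise-free identity sweep uses 5 ms frames. Every random draw is
seeded: acquisitions and traces take explicit seeds, and `run_grid()` draws
per-condition sub-seeds from one master seed, so a grid is bit-reproducible.
`scripts/acceptance.R --seed N --out f.json` re-runs the whole validation
from scratch.

```{r grid, eval = FALSE}
grid <- run_grid(seed = 1)
print(grid)
summary(grid)
```

## What the simulator does and does not show

The synthetic world deliberately reproduces the *structure* of the in vitro
problem — volume conservation through an effective area, AOA > EOA with a
Cc-dependent gap, temporal blunting, noise, partial voluming, beat
averaging — under a known ground truth. Passing tests therefore demonstrate
that the pipeline measures what it claims to measure when its model
assumptions hold. They do not demonstrate robustness to what the simulator
omits: bSSFP image formation and its artifacts, eddy-current phase offsets,
background phase errors, valve annulus motion through the imaging plane,
non-circular or eccentric jets, leaflet mechanics, arrhythmia, pressure
recovery, insonation-angle error in Doppler, or spectral (FFT) Doppler
processing. The pressure-half-time EOA is intentionally not implemented.
Real-scanner numbers (correlations of 0.99, sub-mL biases) depend on the
physical loop and are not expected to be bit-reproduced here; the package's
claim is directional and structural fidelity plus exact internal arithmetic.
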