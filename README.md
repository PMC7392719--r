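# pceoa — phase-contrast CMR assessment of bioprosthetic mitral valve function

Evaluating a bioprosthetic mitral valve (BMV) by Doppler echocardiography is
sometimes technically impossible or unreliable. Phase-contrast (PC)
cardiovascular magnetic resonance measures a per-pixel through-plane
velocity map of the trans-prosthetic inflow jet at every cardiac phase, and
from one such series the valve's function can be quantified without any
ultrasound window:

* **forward flow volume** `FFV = ∫ Q(t) dt`, with `Q(t)` the ROI velocity
  sum × pixel area (mL/beat);
* **time–velocity integral** `TVI = ∫ v_peak(t) dt` over the diastolic
  filling window (cm);
* **effective orifice area** `EOA = FFV / TVI` (cm²) — the mean diastolic
  cross-section occupied by flow at the plane of maximal velocities;
* planimetric **anatomic orifice area** (AOA) and simplified-Bernoulli
  gradients `ΔP = 4 v²` (v in m/s).

`pceoa` is for imaging scientists and method developers who want this
pipeline as runnable, testable code. It implements the PC pipeline, a
continuous-wave Doppler analog (envelope indices and the continuity-style
`EOA = FFV_ref / TVI_Doppler`), method-agreement statistics (Pearson r,
Bland–Altman bias and limits of agreement, Shrout–Fleiss single-measure
ICCs), and — because real scanners and flow rigs are scarce — a pulsatile
flow-loop simulator that generates ground-truth diastolic waveforms,
synthetic PC velocity-map series (NIfTI-1 + JSON sidecar) and CW envelope
traces (CSV) with controllable temporal resolution, noise, partial voluming
and VENC aliasing. An experiment driver reproduces a 24-condition
validation grid (normal 27–33 mm valves and single/double-occluder stenotic
valves at 70/90/110 mL/beat, 70 bpm). See the methods vignette
(`vignettes/pceoa-methods.Rmd`) for the model and every default.

## Worked example

```r
library(pceoa)

wf    <- generate_diastolic_waveform(stroke_volume_ml = 90, heart_rate_bpm = 70)
valve <- valve_model(29)                    # normal 29 mm BMV
print(valve)
#> Bioprosthetic mitral valve, 29 mm, normal
#>   AOA  : 2.70 cm^2
#>   Cc   : 0.62  ->  effective area 1.67 cm^2

series <- synthesize_pc_series(wf, valve, acquisition_params(seed = 7))
analyze_pc(series)
#> PC valve summary
#>   peak velocity :    130.5 cm/s
#>   TVI           :     54.1 cm
#>   FFV           :     89.3 mL/beat
#>   EOA           :     1.65 cm^2
#>   AOA           :     2.85 cm^2
#>   gradients     :      6.8 / 3.8 mmHg (peak/mean)

cw <- synthesize_cw_trace(wf, valve, seed = 8)
analyze_cw(cw, reference_ffv_ml = 90)
#> Doppler valve summary
#>   peak velocity :    143.9 cm/s
#>   TVI           :     56.4 cm
#>   FFV           :     90.0 mL/beat
#>   EOA           :     1.60 cm^2
#>   gradients     :      8.3 / 4.0 mmHg (peak/mean)
```

The valve's true effective area is `Cc × AOA = 1.67 cm²`. The PC pipeline
recovers 1.65 cm² from 17 noisy 48.9-ms frames (FFV 89.3 mL vs 90 mL pumped);
the Doppler analog reads 1.60 cm². The PC peak velocity and TVI sit slightly
below the Doppler values and the PC-EOA slightly above the Doppler EOA —
the error directions expected from coarse temporal sampling on one side and
envelope spectral broadening on the other.

The full validation grid and its agreement reports:

```r
grid <- run_grid(seed = 1)      # 24 conditions x {PC, Doppler, reference}
print(grid)                     # Pearson r and bias per comparison
summary(grid)                   # normal/stenotic group means +/- SD
write_grid_csv(grid, "out")     # conditions.csv, group_summary.csv, agreement.csv
```

A thin CLI over the same functions lives in `inst/cli/pceoa.R`
(`analyze-pc`, `analyze-cw`, `compare`, `run-grid` subcommands).

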