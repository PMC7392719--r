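Package: pceoa
Title: Phase-Contrast CMR Assessment of Bioprosthetic Mitral Valve Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify bioprosthetic mitral valve function from
    phase-contrast (PC) cardiovascular magnetic resonance velocity maps:
    forward flow volume, peak-velocity time-velocity integral (TVI), and the
    effective orifice area derived as PC-EOA = FFV/TVI, alongside a
    continuous-wave Doppler analog pipeline and method-agreement statistics
    (Pearson correlation, Bland-Altman limits of agreement, single-measure
    intraclass correlation). Includes a pulsatile flow-loop simulator that
    generates ground-truth diastolic waveforms, synthetic PC velocity-map
    series (NIfTI-1 with JSON sidecar) and CW Doppler envelope traces, and an
    experiment driver reproducing a 24-condition normal/stenotic valve
    validation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
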