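# aoloop

Control-loop theory, discrete-event simulation, and Shack-Hartmann
wavefront sensing for closed-loop adaptive optics (AO), aimed at the
ophthalmic-imaging regime where loop rates of tens to hundreds of hertz
decide whether cellular-resolution retinal imaging is possible in eyes that
blink, accommodate, wear contact lenses, or move.

The package is for AO system designers and vision scientists who want to
answer, quantitatively: *how fast must my loop run, at what gain, under
which exposure scheme, to correct a given aberration spectrum to the
diffraction limit — and what do sensor noise and DM dynamics cost?*

## The model at its core

An integral-controller AO loop with sensor integration time
`T_int`, readout/processing delay `T_delay`, mirror time constant `T_DM`,
loop rate `R` and gain `g` rejects input aberration power at temporal
frequency `f` by

    |H_reject(s)|^2 = 1 / |1 + G(s)|^2,   s = i 2 pi f,

    G(s) = (1 - e^(-s T_int))/(s T_int) * e^(-s T_delay)/s
           * 1/(1 + T_DM f) * (R g)

and the AO bandwidth `f_c` — the first frequency where the rejection
magnitude reaches 1 — solves the transcendental equation

    T_int (2 pi f_c)^2 (1 + T_DM f_c) sin(pi f_c (2 T_delay + T_int))
      = R g sin(pi f_c T_int).

Bandwidth depends on rate and gain only through the product `R g`, which is
why a 233 Hz discontinuous-exposure loop at gain 1 beats a 342 Hz
continuous-exposure loop limited to gain 0.45. Around this analytic core
the package provides an event-driven simulator of both exposure schemes, a
full Shack-Hartmann forward model with thresholded center-of-gravity
centroiding and 63-mode Zernike reconstruction, an SVD-truncated modal DM
controller, pink-noise and power-law aberration generators, and the PSD
machinery that turns measured spectra into required-loop-rate predictions.

## Worked example

```r
library(aoloop)

cfg <- ultrafast_config()          # 0.126 ms exposure, 233 Hz, gain 1
cat("AO bandwidth:", round(ao_bandwidth(cfg)$f_c, 1), "Hz\n")
cat("vs continuous scheme:",
    round(ao_bandwidth(continuous_config())$f_c, 1), "Hz\n")
cat("rejection improvement over 10 Hz AO:",
    round(low_frequency_rejection_ratio(conventional_config(), cfg)), "x\n")

tc <- timing_config()              # the same loop, cycle-by-cycle
t  <- derive_timing(tc)
cat("loop rate:", round(t$loop_rate), "Hz; latency:",
    round(1e3 * t$latency, 2), "ms\n")
tr <- simulate_convergence(tc, gain = 1, initial_rms = 0.35)
cat("time to diffraction limit:",
    round(1e3 * time_to_threshold(tr, diffraction_limit_rms()), 2), "ms\n")
cat("noise-propagated residual:",
    round(1e3 * noise_propagated_rms(0.100, cfg), 1), "nm\n")
```

prints

```
AO bandwidth: 35 Hz
vs continuous scheme: 28.3 Hz
rejection improvement over 10 Hz AO: 543 x
loop rate: 233 Hz; latency: 3.1 ms
time to diffraction limit: 4.29 ms
noise-propagated residual: 12.8 nm
```

Read: the discontinuous-exposure loop closes its cycle in 4.3 ms (one loop
period) from a 0.35 um static aberration to below the lambda/14 = 0.056 um
diffraction limit; it rejects low-frequency aberration power ~543x more
strongly than a conventional 10 Hz loop; and a 0.100 rad wavefront-sensing
error leaves only ~13 nm on the corrected wavefront — noise is not the
limiting factor.

Higher-level workflows (bandwidth tables, simulated rejection-curve
measurements, exposure-delay scans, per-scenario required-rate predictions,
sensor round trips) are packaged as reproducible experiments:

```r
run_experiment("bandwidth-table", output_dir = "out", seed = 1)
```

or from a shell via `inst/scripts/ao-experiments.R`. The methods vignette
(`vignettes/ao-control-loop-methods.Rmd`) documents the model assumptions,
calibrations and their rationale.

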