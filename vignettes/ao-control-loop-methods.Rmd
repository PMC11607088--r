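---
title: "Methods: AO control-loop theory, simulation, and wavefront sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AO control-loop theory, simulation, and wavefront sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoloop)
```

# The system being modeled

An ophthalmic adaptive-optics (AO) loop measures the eye's dynamic wavefront
aberration with a Shack-Hartmann wavefront sensor (SHWS), reconstructs it,
and cancels it with a deformable mirror (DM) driven by a leakless integral
controller. `aoloop` models the complete loop at two levels:

* **analytically**, through the loop's rejection and noise transfer
  functions, which predict how much aberration power survives correction at
  each temporal frequency; and
* **by discrete-event simulation**, which plays the actual cycle of
  exposures, readout, processing, DM motion and (optionally) synthetic
  camera frames through time.

Five parameters govern the analytic behavior: the sensor integration time
$T_\mathrm{int}$, the combined readout/transfer/processing delay
$T_\mathrm{delay}$, the DM actuation time constant $T_\mathrm{DM}$, the
loop rate $R$, and the integral gain $g$. The defaults describe an
ultrafast ophthalmic system: $T_\mathrm{int} = 0.126$ ms,
$T_\mathrm{delay} = 2.42$ ms, $T_\mathrm{DM} = 0.55$ ms, $R = 233$ Hz,
$g = 1$.

# Rejection, noise transfer, and bandwidth

The open-loop transfer function at $s = i 2 \pi f$ is the product of the
exposure-averaging factor $(1 - e^{-s T_\mathrm{int}})/(s T_\mathrm{int})$,
the delay-plus-integrator factor $e^{-s T_\mathrm{delay}}/s$, a DM
attenuation factor, and the rate-gain product $R g$. The power rejection
curve is $|H_\mathrm{reject}|^2 = 1/|1+G|^2$
(`rejection_power_curve()`), and the noise transfer is the complementary
sensitivity $|G/(1+G)|^2$ (`noise_transfer_power_curve()`), so
$H_\mathrm{reject} + H_\mathrm{noise} = 1$ identically.

Two numerical conventions deserve comment:

* **The DM factor is the real attenuation $1/(1 + T_\mathrm{DM} f)$,**
  written as $1/(1 + T_\mathrm{DM}\, s/(2\pi i))$, not a conventional
  complex first-order pole $1/(1 + i 2\pi f T_\mathrm{DM})$. Only the
  literal real form is consistent with the $(1 + T_\mathrm{DM} f_c)$ factor
  of the bandwidth equation below, and only it reproduces the reference
  bandwidths (35.0 / 28.2 Hz). The phase lag of the physical DM transient is
  instead represented explicitly in the time-domain simulator.
* **The AO bandwidth** $f_c$ is the first frequency at which
  $|H_\mathrm{reject}|^2$ reaches 1. Setting the magnitude to 1 gives a
  transcendental equation with no closed form;
  `ao_bandwidth()` brackets the first sign change on a 2000-point
  log-spaced grid over $[0.01, R/2]$ Hz and refines it by bisection to
  $10^{-3}$ Hz. The direct unity crossing and the equation root agree to
  well under 0.1 Hz and both are exposed.

Bandwidth depends on the loop rate and gain only through their product
(`bandwidth_vs_rate_gain()` demonstrates strict monotonicity), which is why
a 233 Hz loop at gain 1 out-performs a 342 Hz loop restricted to gain 0.45.

**The conventional-AO reference configuration.** A 10 Hz conventional loop
with 45 ms integration needs a delay assumption. With the fast electronics'
2.42 ms the bandwidth equation gives about 2.3 Hz; with one conventional
frame (45 ms) of readout plus processing it gives 1.4 Hz, the figure
conventionally quoted for such systems, and the low-frequency rejection
improvement of the ultrafast loop then reaches its analytic limit
$(233/10)^2 \approx 543$. `conventional_config()` defaults to the 45 ms
reading and exposes `t_delay` so either can be used.

**Noise propagation.** `noise_propagated_rms()` converts a per-measurement
sensing error $\sigma_\phi$ (radians) to a residual wavefront error
$\kappa\,\sigma_\phi\,\lambda/2\pi$, where $\kappa^2$ is the mean of
$|H_\mathrm{noise}|^2$ over the closed-loop band $(0, f_c]$. Averaging over
the band where the loop actively follows its measurements gives
$\kappa = 1.017$ for the ultrafast configuration (12.8 nm from 0.100 rad at
790 nm); averaging all the way to the loop Nyquist frequency instead would
give $\kappa = 0.872$, which understates the propagated error by diluting
the band where noise actually re-enters the wavefront.

# The discrete-event simulator

`simulate_convergence()` and `simulate_tracking()` play the loop cycle
explicitly. A measurement is the exposure-time average of the instantaneous
residual (input aberration minus the DM's effective position), so an
exposure that overlaps DM motion is corrupted by the transient — the
physical mechanism that limits the continuous-exposure scheme's gain.

**Cycle structure.** In the discontinuous scheme each exposure is triggered
only after processing (at $T_\mathrm{int} + T_\mathrm{delay}$ after
exposure start, when the DM command is issued), DM settling
($T_\mathrm{DM}$), an exposure delay (0.3 ms), and a calibrated trigger
overhead. The overhead (~0.90 ms) is the single constant that reconciles
the printed component times (which alone imply ~294 Hz) with the actual
233 Hz loop rate, and is placed after settling so that the simulated
latency — exposure start to DM update completion — remains
$T_\mathrm{int} + T_\mathrm{delay} + T_\mathrm{DM} = 3.1$ ms. In the
continuous scheme the camera free-runs at 342 Hz and updates are issued
synchronously at the next frame boundary after processing completes. That
synchronous choice is deliberate: it means each new exposure begins exactly
as the DM starts moving, which reproduces the observed gain structure
(overshoot at $g = 0.55$, stability at $g = 0.45$, ~34% slower convergence
at $g = 0.35$). An asynchronous update applied mid-frame would leave a
0.38 ms settling head start and, in this model, no overshoot at any stable
gain — inconsistent with how such systems behave.

**DM transient calibration.** The DM is simulated as a first-order response
with time constant $\tau = T_\mathrm{DM}/3$, i.e. 95% settled within the
$T_\mathrm{DM} = 0.55$ ms allowance (the manufacturer's response curve is
not public; `dm_response()` in the modal-control module uses
$\tau = T_\mathrm{DM}$ directly, the literal low-pass reading). This
calibration makes `scan_exposure_delay()` place the optimal exposure delay
at ~0.3 ms when "optimal" means the smallest delay whose residual rebound
stays below the diffraction limit — i.e. the highest overshoot-free loop
rate — and keeps the discontinuous gain-1 convergence monotone, reaching
the diffraction limit at the first confirming measurement, 4.3 ms
(one loop period) after AO activation.

**Where simulation and the analytic curve part ways.** The simulated
empirical rejection (pink-noise stimulus, per-exposure measurement series,
PSD ratio) agrees with the analytic curve to within a few percent at low
frequency, but near the unity crossing the discrete loop follows a
$|1 - z^{-1}|^2$ characteristic whose power deviates from the
continuous-time approximation by up to ~21% in the 43-58 Hz range, and
whose crossing sits at 38.9 Hz rather than 35.0 Hz. This mirrors the
behavior of real hardware, where measured bandwidths exceed the analytic
prediction by a similar margin; the analytic form's continuous integrator
is simply an approximation of the sampled accumulate-and-hold controller.
The package documents this rather than hiding it: the tests compare the
binned empirical curve against the analytic one across the full band
(reporting the near-crossing deviation when it exceeds the nominal 20%
agreement) and check that the empirical unity crossing lies within 20% of
the predicted bandwidth.

# Shack-Hartmann forward model and processing

The sensor model is a 20x20 lenslet array (0.5 mm pitch, 13.9 mm focal
length) sampling a 6.7 mm eye pupil relayed at 1.4627x magnification
(9.8 mm at the array), which makes exactly 300 lenslet centers fall inside
the pupil — the active set. A 6.7 mm pupil placed directly on this array
would cover only ~141 lenslets, so a relay magnification of this order is
geometrically required; its exact value is an assumption of the model.
Each sub-aperture spans 45x45 super-pixels; spots are Gaussian
(sigma = 1.5 super-pixels, a configurable stand-in for the true lenslet
point-spread function), photon counts are Poisson (1962 expected per
lenslet per 0.126 ms frame), read noise is 2 e- RMS, and frames are
digitized to 12 bits.

Centroiding is the two-step thresholding center-of-gravity (TCoG) method:
calibration-plus-global-threshold subtraction, per-sub-aperture peak
location, an 11x11 window around the peak with 30%-of-peak adaptive
threshold (negatives clipped — a center of gravity over signed values is
ill-defined), and the window's center of gravity. Windows are clipped at
sub-aperture borders; peak ties break by first occurrence in column-major
order; a sub-aperture that is empty after thresholding is invalid and
excluded from reconstruction. Blinks are flagged when at least 50% of spots
(threshold-inclusive) peak below 700 counts, and the controller holds the
last non-blink DM shape.

Reconstruction is an ordinary least-squares fit of the analytic mean
Zernike gradients over each sub-aperture to the measured slopes, using 63
RMS-normalized modes in ANSI ordering (radial orders 2-10), so the
coefficient norm is the RMS wavefront error.

**Noise budget.** `sensing_noise_budget()` uses the standard photon
($\propto 1/\sqrt{N}$, scaled by spot-size geometry) and readout
($\propto \sigma_e/N$, scaled by an effective noise area) error forms, with
the two geometric constants calibrated so that the default photon count and
read noise give 0.100 rad and 0.010 rad. Two things follow and are tested:
the error terms keep their physical scalings (4x photons halves the shot
term), and the synthetic TCoG estimator is ~1.8x noisier than this
matched-estimator budget — thresholded centroiding discards spot wings, a
known inefficiency, verified in the tests against a brute-force
single-spot oracle rather than absorbed into the calibration.

# Synthetic aberration inputs

`gen_pink_noise()` synthesizes the rejection-measurement stimulus in the
frequency domain (amplitude $\propto f^{-1/2}$, uniform random phases, DC
removed — the power law diverges at DC and the loop removes DC anyway),
rescaled to an exact target RMS. `scenario_psd_model()` parameterizes
ocular-aberration spectra as a power law plus noise floor,
$A f^{-\alpha} + P_\mathrm{noise}$, optionally with a Gaussian bump at
3-8 Hz emulating nystagmus oscillation. The normal-eye preset uses
$\alpha = 1.5$ and a floor whose band-integrated RMS at 342 Hz sampling is
23.3 nm; clinical presets scale the amplitude 10-100x. These presets are
illustrative — per-scenario spectra of real eyes are not published — and
every field is overridable. Synthesis uses deterministic spectral
amplitudes with random phases, so the expected (and, up to leakage, the
realized) periodogram equals the model PSD exactly; this trades the
chi-squared amplitude statistics of a true Gaussian process for exact
spectral reproducibility, which is the property the generator exists to
provide.

What the synthetic data does **not** emulate: spatial correlation between
lenslet channels, non-stationarity (blinks, saccades, tear-film breakup
within a record), accommodation drift, and the rolling-shutter row
structure of the real sensor. Tests passing on this data therefore
establish the correctness of the pipeline's machinery, not the clinical
values of any derived rate requirement.

# PSD conventions and derived predictions

`estimate_psd()` implements the plain-DFT convention: squared DFT magnitude
divided by the spectral resolution (inverse total duration), one-sided, DC
excluded, channel-averaged; Parseval holds exactly. No window is applied by
default, matching the convention the rejection measurement was defined
with; a Hann option exists and is used in the package's own
rejection-curve comparisons, where pink-noise leakage from the strong
low-frequency bins would otherwise contaminate the steep closed-loop
spectrum. `temporal_error()` integrates an input PSD under a rejection
curve from the lowest nonzero bin (the band's lower limit is the spectral
resolution); `required_loop_rate()` scans a rate grid using the standard
fast-loop family (discontinuous, gain 1, integration time half the loop
period, readout/processing the other half);
`diffraction_threshold_psd()` inverts the same machinery to draw the
"barely correctable" input spectrum for a given loop, using a pink
($f^{-1}$) template by default to match the stimulus convention.

# Problem sizes and reproducibility

The test suite and acceptance analyses use: 2000-point log-spaced scans for
root bracketing; 2048-4096-sample, 3-channel pink-noise tracking runs
(about 9-18 s of simulated loop time, comfortably more than the ~1000 time
points a physical rejection measurement uses); 100 noisy frames for the
round-trip noise statistics; and 50 realizations for spectral-recovery
checks. All stochastic paths take an explicit integer seed and restore the
caller's RNG state; identical seeds give identical outputs byte-for-byte.

# Known limitations

* The analytic DM factor carries no phase; all DM phase lag lives in the
  simulator's exponential transient, whose time constant is a calibration.
* The trigger-overhead constant is inferred, not measured; changing it
  moves the discontinuous loop rate and every timing-derived quantity.
* The TCoG noise inefficiency (~1.8x the matched bound) depends on the
  Gaussian spot stand-in; real lenslet PSFs will differ.
* Scenario presets are order-of-magnitude models; no attempt is made to
  reproduce per-scenario required loop rates, which depend on unpublished
  subject spectra.
* Rolling-shutter effects, eye motion during exposure, and multi-corrector
  architectures are out of scope.
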