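---
title: "Closed-loop optical voltage clamp: model, controllers and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optical voltage clamp: model, controllers and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovclamp)
```

## The problem

An all-optical voltage clamp holds the membrane potential of an excitable
cell at a setpoint using light only: a genetically encoded voltage indicator
(a far-red rhodopsin whose fluorescence scales approximately linearly with
voltage) provides the measurement, and a tandem pair of spectrally opposed
optogenetic actuators — a red-shifted depolarizing cation channel and a
blue-shifted hyperpolarizing anion channel at fixed stoichiometry — provides
the actuation. A monochromator steers a single wavelength between roughly
400 and 600 nm; moving it red recruits the depolarizer, moving it blue the
hyperpolarizer, so one scalar control variable spans both signs of current.
The controlled variable is the bleach-corrected relative fluorescence change
dF/F0 (percent), sampled once per camera frame at up to 100 Hz.

`ovclamp` is a digital twin of that loop: a simulated cell ("plant"), a
fluorescence sensor model, the live bleach correction, the feedback laws,
session orchestration with the field's results-file format, and the offline
statistics used to convert optical readouts into volts and picoamperes.
Everything a physical rig would provide is simulated, so closed-loop
behavior, calibration procedures and analysis code can be exercised end to
end, reproducibly, on a desk.

## Plant model

The cell is a single-compartment membrane,

$$C \frac{dV}{dt} = -g_L (V - E_L) + I_{dep} + I_{hyp} + I_{Ca}
  + I_{event} + I_{inject} + g_L \, \eta(t),$$

with each photocurrent a first-order photoconductance:
$I = I_{max}\, a \,(V - E_{rev})/(V_{ref} - E_{rev})$, where the gate $a$
relaxes with time constant $\tau_{act}$ toward the spectral drive — the
channel's Gaussian action spectrum evaluated at the monochromator
wavelength, times intensity, plus the imaging laser's crosstalk onto the
red-shifted channel — clipped to $[0,1]$. The driving force is normalized to
1 at the reference (resting) potential, so `max_current` is the current a
fully driven channel passes at rest. Depolarizing current is positive
throughout the package. Integration is explicit Euler with a fixed 0.1 ms
inner substep regardless of the frame period; gates advance by their exact
exponential solution and the voltage update is affine at fixed gating, so
halving the substep changes a 1 s trajectory by well under 0.5 % (asserted
in the tests).

This is deliberately the simplest structure able to reproduce the published
closed-loop observables: the controllers, not the biology, are the subject.
Multi-compartment morphology, Hodgkin–Huxley channel libraries and
photocycle states beyond one first-order gate are out of scope.

### Membrane noise

Spontaneous fluctuations are modeled as an Ornstein–Uhlenbeck process
$\eta$ (mV units, injected as a current through $g_L$) with stationary SD
`noise_sd` and correlation time `noise_tau`. Two printed observables pin
both parameters for the reference muscle preset: the free-running
fluorescence fluctuation (1.89 % dF/F0 SD) and the fluctuation while
clamped at −5 % (≈0.78 %). White per-substep noise cannot reproduce the
second number at a 100 Hz control rate — a sampled-data controller cannot
cancel noise that is uncorrelated from frame to frame — whereas the slow
synaptic background that the fluctuations are attributed to is strongly
correlated. The calibrated defaults are `noise_sd = 9.3` mV and
`noise_tau = 700` ms; both SDs are measured through the full pipeline
(bleach fit, baseline, correction), exactly as an experimenter would
measure them.

### Spectral and electrical constants of the reference preset

The body-wall-muscle (`bwm`) preset was solved numerically so that, at
once:

* the steady photocurrent versus wavelength at a clamped −24 mV
  (patch convention, inward negative) is nearly linear over 420–580 nm
  (R² ≈ 0.98) with an OLS slope of −1.21 pA/nm;
* the crosstalk-compensation wavelength (zero net photocurrent at rest
  under the imaging laser) is ≈ 516 nm;
* 470 nm light from darkness hyperpolarizes the cell by ≈ 15 mV;
* an open-loop wavelength step reaches 90 % of its plateau in ≈ 24 ms;
* holding +5 % dF/F0 requires a steady wavelength near 555 nm, and the
  400/600 nm limits leave headroom beyond ±5 %.

The resulting action-spectrum widths (σ ≈ 101 and 112 nm) are effective
widths: they absorb intensity nonlinearities and spectral overlap, not just
the photochemistry, which is why they are broader than a rhodopsin's
photometric action spectrum. The total 420–580 nm current range comes out
at ≈172 pA against the published "~190 pA"; the two printed anchors (range
and regression slope) are not exactly consistent with each other under any
smooth two-channel spectrum, and the slope was prioritized because the
calibration regression is the quantity carried forward into unit
conversion. The hyperpolarizer reversal (−120 mV) is likewise an effective
driving-force parameter rather than a Nernst potential.

### Intrinsic action potentials

Spontaneously active presets (`pharynx`, `dvb`) schedule stereotyped AP
current waveforms: an exponential rise to a plateau and an exponential
repolarization, with the full width at half maximum set directly. A
regenerative trigger gates each scheduled event: a sub-threshold pacemaker
drive (fraction `floor` of the event current, rising slowly with
`pacemaker_tau`) must carry the voltage across `vhalf` within a trigger
window, otherwise the attempt fails and the drive is withdrawn. A purely
injected waveform cannot reproduce dynamic-clamp suppression — the
monochromator's counter-authority is smaller than a full AP current, so
only aborting the regenerative step can silence the cell, which is also the
mechanism the original experiments describe. Event amplitudes are
leak-referenced currents calibrated so the *observed* free-running
fluorescence amplitudes match the published values (pharynx ≈ 26 % dF/F0,
FWHM ≈ 120 ms; DVB ≈ 8 %, FWHM ≈ 0.5 s), because the open photoconductances
shunt part of the drive. Event schedules in these presets are aligned to
the clamp phase: the calibration recording is taken before rhythmic
activity starts (experimenters time acquisitions to quiescent stretches),
which keeps the bleach fit and baseline uncontaminated; the flagged-fit
path still handles AP-contaminated calibrations gracefully.

## Sensor model

Expected photons per frame are
$N = N_0 (1 + s\,(V - V_{ref})/100)\, B(k)$ with $s$ the fluorescence
sensitivity (percent dF/F0 per mV; 10/22 in muscle, 10/65 in the DVB
neuron, 0.21 in the mammalian preset) and
$B(k) = (a e^{-bk} + c)/(a + c)$ the multiplicative bleach profile
(defaults a = 0.25, c = 0.75, b = 5×10⁻⁴ per frame, i.e. ≈16 % signal loss
over a 20 s calibration). Bleaching multiplies the whole signal, which is
the assumption under which the ratio correction below is exact. Shot noise
uses the Gaussian approximation to Poisson statistics (all presets have
N ≥ 10⁴ photons, where the approximation error is negligible): gray values
are $\mathrm{round}(g \cdot \mathcal{N}(N, \sqrt N))$ with camera gain
g = 1 ADU/photon. At the default 1.8 million photons per frame the relative
shot noise is 1/√N ≈ 0.075 %, the published photon-budget floor. Spatial
imaging (PSF, pixels, ROI segmentation) is not modeled.

## Bleach correction and dF/F0

During the calibration phase (default 2000 frames = 20 s at 100 Hz) raw
gray values are fitted with $a e^{-b\,\mathrm{frame}} + c$ by
Levenberg–Marquardt, with initial guesses from the first/last deciles and a
log-linear fit; fit quality is $R^2 = 1 - SSE/SSD$. Every later frame is
corrected by the offset ratio $(a + c) / (a e^{-bk} + c)$ (identity at
frame 0 and for b = 0). At the last calibration time point the first 50
corrected gray values are averaged into the baseline F0 — the arithmetic
mean, the plugin-conventional estimator — and thereafter
$dF/F0 = 100\,(F_{corr} - F0)/F0$. A non-convergent fit falls back to a
flat profile with a flagged, low R²; a fit predicting non-positive offsets
anywhere in the run aborts the session with a diagnostic. Short
calibrations identify $b$ poorly and the extrapolated correction then
drifts by a few percent over long clamp phases; the 20 s default exists
precisely because it pins the decay rate (this is visible in the
dynamic-clamp presets, which need an accurate baseline).

## Controllers

**Decision-tree integral controller.** Each frame, if the measured dF/F0 is
within the tolerance band of the holding value, the wavelength is held
(inclusive comparison, so a deviation exactly at the edge holds — the band
is where the value is *allowed* to fluctuate). Otherwise the wavelength
moves by $K_I \cdot e$, $e = |target - dF/F0|$, in the direction
`increment_sign * sign(target - dff)`, and is clipped to the monochromator
limits; status is `holding`, `adapting` or `limit_reached` accordingly.
$K_I$ is in nm per percent per frame, because the update law indexes by
frame. The default gain (2.5 for the step-clamp presets) was chosen
empirically on the reference plant — as the original gain was — to meet the
published transition times and accuracy fractions; the dynamic-clamp
presets use a larger gain (4) and a ±0.005 % tolerance.

**PID.** $u = K_P e + K_I T_a \sum e + K_D (e - e_{prev})/T_a$ with signed
error, positioned about the calibration wavelength
($\lambda = \lambda_0 + u$). The integral memory freezes while the
wavelength is clipped (anti-windup; the original behavior at the limits is
unstated, and an unbounded sum would badly overshoot on release). Inside
the tolerance band the wavelength holds, mirroring the decision tree.

**Ziegler–Nichols.** The proportional gain is ramped on the noiseless plant
until the closed loop sustains oscillation; the critical gain and
oscillation period give $K_P = 0.6 K_{P,crit}$, $T_n = 0.5 T_{crit}$,
$T_v = 0.12 T_{crit}$, $K_I = K_P/T_n$, $K_D = K_P T_v$. At a 100 Hz frame
rate the critical period is only a few frames, outside the method's
continuous-time assumptions, and the raw tuned loop is bounded but
marginally oscillatory; with the Kalman filter smoothing the measurement
the tuned loop converges cleanly. This mirrors the original finding that
the PID/Kalman variant "did not increase overall system performance".

**Kalman filter.** Scalar, with system and output matrices fixed at 1
(constant-dynamics smoothing): predict $x^* = \hat x$, $P^* = P + Q$; gain
$K = P^*/(P^* + R)$; correct. Initialization uses the first
calibration-phase dF/F0 and $P_0 = R$. The tests assert the estimate and
variance against the scalar Riccati fixed point.

## Sessions, protocols and the results file

One controller update per camera frame (the loop is sampling-rate-limited,
as the original is); the commanded wavelength takes effect on the next
frame; monochromator actuation latency (~100 µs) is not modeled at 10 ms
frames. The calibration phase runs under the imaging laser plus the start
(compensation) wavelength. Protocols: three/four-step clamps, the 11-step
pseudo-I/V between chosen limits (summarized by the mean of the last 25 %
of each step), open-loop optical current clamp (pulses and ramps), and
on-the-run target schedules (live target changes applied at frame
boundaries). Results are written as UTF-8 text with `# key: value` headers
(all protocol parameters, bleach a/b/c/R², frame rate) and a tab-separated
frame table with status codes `C`/`H`/`A`/`L`; numeric formats are fixed so
a seeded rerun is byte-identical.

## Offline analysis

Calibration regressions are ordinary least squares with
heteroscedasticity-consistent (White/HC0) standard errors and the White
test in its standard auxiliary-regression form (squares and
cross-products; with one regressor, $e^2 \sim x + x^2$, $LM = nR^2$,
χ² with 2 df). The published constants — membrane potential =
−30.27 + 2.25 · dF/F0 (mV per percent) and current = 607.06 − 1.21 · λ
(pA per nm, inward negative) — ship as defaults for unit conversion.
Transition time is counted from a step's first frame to its first in-band
frame (0 if it starts inside; saturated steps are flagged and feed the
saturation fraction). Control quality reports the within-band fractions at
the tolerance and half the tolerance, per-step transition times, the
fraction of limit-clipped frames, and an r.m.s.-deviation time course in
100 ms bins with transition periods excluded. AP detection uses topographic
prominence with amplitudes from the local baseline, FWHM by linearly
interpolated half-maximum crossings (the interpolation rule is a choice;
none is stated in the source material), and a rise time constant from the
10–90 % span of the rising flank ($\tau = t_{10-90}/\ln 9$), the span being
our choice of fit window. Pseudo-I/V difference curves convert both curves
to mV and pA and form the *intrinsic* current difference per pF: because
the optically applied current cancels the intrinsic current at steady
state, the intrinsic difference for curves a − b equals converted(b) −
converted(a); this sign convention is what makes a gain-of-function Ca²⁺
channel appear as an inward (negative) difference current above 0 % dF/F0.

## Synthetic calibration data

`simulate_voltage_calibration()` and `simulate_current_calibration()`
emulate the two simultaneous-calibration experiments: 80 paired (dF/F0
target, measured voltage) observations over −5…+5 % and 72 paired
(wavelength, steady clamp current) observations over 420–580 nm, from the
reference maps plus heteroscedastic scatter (SD growing toward the
extremes, which is why robust standard errors are the right tool) sized to
land near the published R² of 0.8. The generating slopes are the map
slopes: 2.2 mV per percent and ≈−1.21 pA/nm.

## What the generator does and does not emulate

The simulator reproduces: the linear fluorescence–voltage mapping with
realistic photon budgets, exponential bleaching and its live correction,
sampled-data feedback with tolerance band and hard wavelength limits,
bidirectional spectral actuation with laser crosstalk, slow membrane noise
with pipeline-level fluctuation statistics, stereotyped regenerative APs,
and the published calibration relations. It does not emulate: spatial
imaging and ROI selection, motion artifacts, channel desensitization or
photocycle depletion over minutes, cell-to-cell expression variability
(beyond the noise model and the heteroscedastic calibration scatter),
pharmacology, or behavior. Passing tests therefore validate the control
and analysis machinery under the stated model, not the biology of any real
preparation.

## Problem sizes

The default study conditions used by the tests and the acceptance analysis:
closed-loop accuracy pools the four-step protocol (0, −5, +5, 0 %; 2 s per
step) after a 20 s calibration over 20 seeded runs at 100 Hz; calibration
regressions use 100 seeds of n = 80 / n = 72 synthetic data sets;
dynamic-clamp checks use 10 s of 4 Hz pharyngeal activity. Unit tests run
on shortened noiseless sessions where the closed-form fixed points are the
oracle.

## Example

```{r example, eval = FALSE}
su <- ovc_setup("bwm")
prot <- ovc_protocol(targets = c(0, -5, 5, 0), frames_per_step = 200,
                     calibration_frames = 2000, seed = 1)
ses <- run_session(prot, su$plant, su$sensor, su$controller)
summary(ses)
plot(ses)
piv <- run_pseudo_iv(c(-5, 5), prot, su$plant, su$sensor, su$controller)
difference_iv(piv, piv, capacitance = 50)   # trivially zero
```
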