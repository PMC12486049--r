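---
title: "Transabdominal fetal oximetry in silico: model, signal chain, and estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transabdominal fetal oximetry in silico: model, signal chain, and estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Transabdominal fetal oximetry (TFO) estimates fetal arterial oxygen
saturation (fSpO~2~) by shining near-infrared light on the maternal abdomen
and sensing the diffusely reflected photoplethysmogram (PPG) at several
source–detector distances (SDDs). `tfoptics` implements the full in-silico
pipeline: photon transport in a layered pregnant-abdomen model, the forward
optics of the pulsatile fetal signal, photodetector noise, a synthetic
multiplexed PPG extraction chain, and a neural fusion estimator that maps
multi-detector features to fSpO~2~. This vignette explains the models, the
tunable parameters and their defaults, the numerical choices, and what the
package's tests do and do not establish about real recordings.

## Tissue model

The abdomen is a flat stack of four homogeneous layers: maternal abdominal
wall (thickness `dm`, 4–34 mm), uterus wall (5 mm), amniotic fluid (1 mm),
and semi-infinite fetal tissue, so the fetal depth is `dm + 6` mm.
Scattering coefficient, anisotropy (`g = 0.9`) and refractive index are
static per layer and wavelength; only the absorption of the two perfused
layers responds to hemodynamics. For those layers,

$$\mu_a = 0.05\,(\mu_{a,\text{arterial}} + \mu_{a,\text{venous}})
        + 7.84\times10^{7}\,\lambda^{-3.255}\ \text{mm}^{-1},$$

with the wavelength in nm: 5% arterial plus 5% venous blood by volume on a
power-law non-blood baseline (melanin is not modelled). Whole-blood
absorption is `[Hb]` times the saturation-weighted mix of the oxy- and
deoxy-hemoglobin extinction coefficients, taken from the standard compiled
hemoglobin spectra, converted to mm^-1^ per g/L, and embedded for
600–1000 nm with linear interpolation. Venous saturation defaults to 0.75
of arterial — the common clinical convention; the literal alternative
reading "venous is 25% of arterial" is unphysiological. Both the venous
fraction and the 5% blood-volume fractions are exposed as arguments.

A fetal cardiac cycle is represented by two static states: a diastolic
baseline and a systolic state in which fetal `[Hb]` is raised by 2.5%. The
increment is attached to systole (peak blood volume, hence peak absorption
and trough intensity), so the Exponential Pulsation Ratio defined below is
at least 1.

## White Monte Carlo transport

`simulate_paths()` propagates a pencil beam with exponential step sampling
on `mu_s`, Henyey–Greenstein scattering, and unpolarized Fresnel
reflection/refraction at index mismatches (air 1.0 / tissue 1.4 / amniotic
1.33); the specular entry loss is a launch weight. No absorption is applied
in flight ("white" Monte Carlo): each detected photon's per-layer
pathlengths `L_j` are tabulated, and any absorption assignment is applied
afterwards as `exp(-sum_j mu_a,j L_j)`. One simulation per geometry and
wavelength therefore serves the entire hemodynamic sweep. An in-flight
absorption-weighting mode that consumes the identical random stream exists
purely as a test oracle: its paths coincide photon for photon, and the unit
and acceptance suites require agreement to 1e-10.

Detectors exploit the cylindrical symmetry of the flat model: a photon
exiting at radius `r` is collected by the annulus with `|r - sdd| <= 2` mm.
The default grid is 20 rings from 10 to 95 mm. Ring collection changes the
absolute intensity scale by a purely geometric factor relative to discrete
surface detectors; the factor cancels in every ratio the pipeline uses
(EPR, RoR, fetal sensitivity). `intensity(..., per_area = TRUE)` divides by
the annular area and is the quantity compared with diffusion theory.

Numerical guards: photons are terminated beyond a 150 mm lateral radius,
beyond 2000 mm total pathlength, and — in the four-layer model — beyond
per-layer budgets (`tissue_budgets()`: 350 mm maternal wall, 600 mm uterus,
250 mm fetal tissue). The budgets exploit the fact that those layers absorb
at >= 0.016–0.05 mm^-1^ over the whole physiologic sweep, so the truncated
photons would re-enter every reweighted result with relative weight below
about e^-9; the saving is severalfold in runtime. The optically thin
amniotic fluid, which can guide photons laterally by total internal
reflection, gets no budget. The homogeneous-medium validation runs without
budgets. The RNG is a seeded xoshiro256+ with compiler-independent
uniforms, so tables are reproducible bit-for-bit across builds; the seed
and a geometry fingerprint are stored in every table and checked on reuse.

Validation: the simulator's spatially resolved reflectance for a
semi-infinite homogeneous medium (`mu_a = 0.01` mm^-1^, `mu_s' = 1` mm^-1^,
matched index) is compared against the extrapolated-boundary dipole
solution of diffusion theory at SDD 20–60 mm; with 10^7^ photons the two
agree within 15% everywhere, which is the expected accuracy of the
diffusion approximation itself at these distances.

## EPR, RoR, and fetal sensitivity

With `I_1` the systolic-trough and `I_2` the diastolic-peak intensity, the
Exponential Pulsation Ratio at one detector and wavelength is
`EPR = I_2 / I_1 = (2 AC + DC) / DC`. On a pathlength table it reduces to a
ratio of fetal-layer exponential expectations weighted by the (unchanged)
non-fetal attenuation; `epr()` is tested to satisfy that identity exactly.
The conventional two-wavelength feature is recovered as
`RoR = ln(EPR_{wl1}) / ln(EPR_{wl2})`, which tends to the familiar ratio of
AC/DC ratios for small pulsation. Fetal sensitivity is
`|dI/dmu_a,fetal| / (|dI/dmu_a,fetal| + |dI/dmu_a,maternal|)`, computed
from the same table; it rises with SDD toward a plateau as essentially all
detected photons become fetal-sensitive.

Raw per-ring EPR-vs-SDD curves carry Monte Carlo noise, amplified by the
ratio. `smooth_epr_curve()` therefore takes divided central differences
(one-sided at the ends, actual spacings on non-uniform grids), applies a
2-point moving average to the difference sequence, and reintegrates from
the first point; affine curves are exact fixed points. The smoothed curve
is then linearly interpolated at the probe SDDs {15, 33, 46, 68, 94} mm,
and these interpolated values feed all downstream analysis (the raw path
remains available via `interpolate = FALSE`).

Two forward-model properties worth stating honestly:

* **Saturation–geometry ambiguity is reproduced.** Distinct (fetal depth,
  saturation) pairs produce single-detector EPRs that agree within Monte
  Carlo error at one SDD while their multi-detector EPR vectors separate by
  many standard errors — the motivation for detector fusion. The
  acceptance suite constructs such a pair at depths 10 and 11 mm, 735 nm,
  with photon-resampling bootstrap standard errors.
* **EPR isolation from the maternal layer is only approximate.** The
  textbook derivation of EPR assumes the joint pathlength density
  factorizes from the fetal component. On real tables the within-ring
  covariance between maternal and fetal pathlengths is positive, so at
  `dm = 14` mm and SDD 46 mm a ±20% maternal absorption change moves EPR
  by a few 10^-3 (the acceptance script reports the measured shift). Worse for single-detector
  sensing, the EPR response to sweeping fetal saturation 20→60% at that
  same detector nearly cancels at 735 nm — the pulsation-gap decrease and
  the fetal-pathlength reweighting act in opposite directions — leaving a
  residual smaller than the maternal coupling. Both shifts are measured
  with the variance-reduced first-order forms (`epr_layer_shift()`,
  `epr_perturbation_shift()`) and reported by `scripts/acceptance.R`; the
  acceptance test encoding the idealized expectation (maternal coupling
  below one tenth of the fetal response) fails on the faithful model and
  is left failing deliberately. Saturation information survives in the
  *pattern* across detectors and wavelengths — which is why the fusion
  estimator works while any single-detector readout cannot.

## Photodetector noise

Shot noise `sqrt(2 q B i_k)` and thermal noise `sqrt(4 k_B T B / R)` are
injected as zero-mean Gaussian current noise, converted to intensity units
through the responsivity (0.60 A/W) and a source-power scale. Bandwidth
(80 Hz), temperature (300 K), gain resistance (10 MOhm) and the source
power (10 mW) are configuration values; the source power sets the
effective SNR and is reported alongside any noisy result. Scenario 1 is
shot-only; scenario 2 applies per-detector gains chosen to equalize
received power (`compute_gains()`) and adds the root-sum-square of shot
and thermal noise. Systolic and diastolic intensities receive independent
draws, as they are separate measurements in time. Dark current, 1/f noise
and motion artifacts are out of scope.

## Synthetic PPG and the extraction chain

`synthesize_ppg()` emulates a frequency-multiplexed acquisition: per
(detector, wavelength) the baseband is DC plus maternal cardiac, maternal
respiratory and fetal cardiac sinusoids, each frequency-modulated by its
rate trace (defaults within 1.1–2, 0.2–0.33 and 1.5–3.5 Hz), multiplied by
its LED toggle waveform (690 and 940 Hz carriers) and summed at
8000 samples/s. The toggle waveform is the 50%-duty square wave
*band-limited below Nyquist* (`square_carrier()`): harmonics above Nyquist
would alias into the demodulated band as spurious tones that a real
front end's anti-alias filter removes before sampling. The DC and fetal AC
levels can be taken directly from forward-engine intensities so the
recovered EPR has a physics-grounded target; the stored truth is
`EPR = (2 AC + I_1) / I_1` with `I_1 = DC - AC` the systolic trough.

Extraction mirrors the hardware chain: synchronous complex demodulation at
the carrier fundamental (the square-wave fundamental factor makes the
documented scale constant pi), two-stage Butterworth low-pass filtering and
decimation 8000 → 800 → 80 samples/s with a 30 Hz final cutoff (samples
within the filter settling time are flagged, not silently returned); the
DC/`I_1` series from a lower envelope implemented as a morphological
opening (rolling minimum then maximum over one fetal cardiac period, odd
window, edge-padded — chosen because the opening is exactly idempotent and
never exceeds the signal); the fetal AC from lock-in detection at the
known instantaneous fetal heart rate with a 4 s Hann-weighted window
(resolves the fetal line from maternal clutter at their minimum separation
while tracking rate drift); and the EPR series `(2 AC + DC) / DC` smoothed
by a 90 s centered moving average. In synthetic mode the FHR trace is
ground truth, standing in for the carotid-line reference of an animal
experiment; FHR estimation from the PPG itself is out of scope. The
round-trip requirement — recovered EPR within 1% of truth without clutter
and 3% with clutter, per channel — passes with roughly an order of
magnitude of margin.

## Fusion estimator

Each sample is the 10-vector of interpolated EPRs (5 SDDs x 2 wavelengths)
or, for the baseline, the 5-vector of per-detector RoRs; the label is
fetal arterial saturation in percent. The estimator is a multilayer
perceptron with hidden widths halving from 64 to 8, each hidden block
linear → ReLU → batch normalization (the order is a switch), a single
linear output, Adam (lr 1e-3, weight decay 1e-4), batch size 32, up to 300
epochs with patience-25 early stopping and best-weights restore; weights
start normal with He scale, biases at zero. Features and labels are
standardized on training-set statistics inside the trainer (undone at
prediction) so these optimizer settings remain meaningful at desk-scale
sample counts. The network is implemented in plain R matrix code —
including batchnorm backpropagation — because no pre-installed package
provides this architecture; a closed-form parameter-count oracle and
linear-map recovery tests guard the implementation.

Validation schemes follow the two study designs: a per-geometry 80/20
random split for simulation data, and contiguous 5-fold temporal splits
with inverse-round-size sample weights for time-series data, where a
random split would leak information between overlapping windows. Metrics
are MAE, the standard deviation of absolute errors, and Pearson's r with a
two-sided p-value (reported, never used as a gate).
`run_comparison()` trains the same network five times with different
initializations on paired EPR/RoR datasets and averages the metrics; the
improvement columns are `(RoR - EPR)/RoR * 100` for errors and the
sign-flipped analogue for r.

One degenerate case needs a rule: at deep geometries a near detector may
collect no fetal-sensitive photon, making both wavelengths' EPR exactly 1
and RoR the 0/0 limit; `feature_matrix(type = "ror")` encodes such
detectors as 0 (no pulsation information). The strict `ror()` function
still refuses a unit denominator.

## Problem sizes and what the tests show

The published study conditions are cluster-scale (10^9^ photons per
geometry, 31 depths, ~16,000 hemodynamic samples per depth). The package's
default desk-scale study — chosen once as a faithful miniature, not tuned
to any outcome — uses 5 maternal-wall thicknesses {4, 14, 21.5, 27.5,
34} mm (fetal depths 10–40 mm), 3x10^5^ photons per geometry and
wavelength, and a 450-point hemodynamic grid per depth (sm {0.90, 0.94,
0.98} x [Hb]m {110, 140} g/L x sf 10–70% in 2.5% steps x [Hb]f {120, 150,
180} g/L), for 2250 samples. At this scale the EPR-feature estimator
outperforms the RoR baseline in both MAE and correlation with a margin
comparable to the full-scale report, but the absolute MAE is a few points
higher — Monte Carlo feature noise at 3x10^5^ photons and a 30x smaller
training set are the expected causes. The suite asserts ordering and
order of magnitude, not the full-scale values.

What passing tests do *not* show: the synthetic PPG contains no motion
artifacts, probe-coupling drift, curved or heterogeneous anatomy, or
non-sinusoidal pulse shapes, so round-trip accuracy here bounds only the
algorithmic part of the chain; and the estimator is validated within the
simulated geometry distribution — generalization to unseen depths is an
extrapolation problem and is known to be poor.

## Reproducibility

Every stochastic stage takes an explicit seed; photon tables embed the
seed and a geometry fingerprint, and `pipeline_run()` writes a JSON
manifest (config snapshot, seeds, fingerprints, timings) next to its CSV
features and metrics, reusing intermediates only when the config
fingerprint matches and always training from the serialized features so
reruns reproduce byte-identical artifacts. Training is additionally
subject to the numeric backend: a threaded BLAS may reassociate sums, so
fitted metrics are reproducible to ~1e-3 rather than bitwise.
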