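# tfoptics

Transabdominal fetal oximetry (TFO) by diffuse optics, end to end and in
silico. TFO shines two near-infrared wavelengths on a pregnant abdomen and
senses the diffusely reflected photoplethysmogram (PPG) at several
source–detector distances (SDDs); the faint fetal pulsation buried in that
mixed maternal–fetal signal carries the fetal arterial oxygen saturation
(fSpO₂), the quantity clinicians lack during labor when deciding whether a
fetus is hypoxic. `tfoptics` is aimed at biomedical-optics researchers who
want to study the physics and signal processing of that measurement without
hardware: it simulates the tissue, the detector noise, the multiplexed
acquisition, and the estimation pipeline, all with seeded reproducibility.

The package provides:

* **White Monte Carlo photon transport** (Rcpp) through a flat four-layer
  pregnant-abdomen model (maternal wall / uterus / amniotic fluid / fetal
  tissue), recording each detected photon's per-layer pathlengths `L_j`.
  Absorption is applied afterwards as `exp(-Σ μ_a,j L_j)`, so one
  simulation serves every hemodynamic configuration of its geometry.
* **A forward engine** for normalized intensity, fetal sensitivity
  `|∂I/∂μ_a,f| / (|∂I/∂μ_a,f| + |∂I/∂μ_a,m|)`, the Exponential Pulsation
  Ratio `EPR = I₂/I₁ = (2·AC + DC)/DC` per detector and wavelength, the
  conventional Ratio-of-Ratios baseline `RoR = ln EPR_λ1 / ln EPR_λ2`,
  EPR-vs-SDD curve smoothing, and pathlength-distribution summaries.
* **Photodetector noise**: shot `√(2qBi)` and thermal `√(4k_BTB/R)`
  current noise with per-detector gain normalization.
* **A synthetic PPG pipeline**: frequency-multiplexed dual-wavelength
  acquisition (690/940 Hz LED toggling at 8000 samples/s) with maternal
  cardiac, respiratory and fetal components, and the extraction chain —
  synchronous demodulation, decimation to 80 Hz, lower-envelope DC,
  lock-in fetal AC at the instantaneous fetal heart rate, EPR series.
* **A fusion estimator**: a from-scratch MLP (widths 64→32→16→8→1, ReLU +
  batchnorm, Adam, early stopping) mapping 10 EPRs (or 5 RoRs) to fSpO₂,
  with per-geometry random splits, contiguous temporal folds,
  inverse-round-size weights, and broom-style `tidy()`/`glance()`.

## Worked example

```r
library(tfoptics)

# one geometry: 14 mm maternal wall (fetal depth 20 mm), 735 nm
tab <- simulate_paths(tissue_layers(735, dm = 14), 3e5, seed = 1,
                      l_layer_max = tissue_budgets())
pp  <- pulsation_pair(build_state(14, maternal = blood_state(120, 0.97),
                                  fetal = blood_state(160, 0.40), 735))
s <- tab$detectors$sdd[9]  # the 45.8 mm ring
fetal_sensitivity(tab, mu_assignment(pp$diastole), s)
#> [1] 0.008832011
epr(tab, mu_assignment(pp$systole), mu_assignment(pp$diastole), s)
#> [1] 1.001987
```

A fetal sensitivity of 0.0088 says that at a 46 mm detector roughly 0.9%
of the absorption-derivative signal originates in the fetal layer, 20 mm
deep; the EPR of 1.002 is the diastole/systole intensity ratio whose
excess over 1 encodes the fetal pulsation seen by that detector — both
grow substantially at larger SDDs. Sweeping hemodynamics and training the
fusion estimator:

```r
cfg <- tfo_config(sweep = list(dm = c(4, 14, 21.5, 27.5, 34)),
                  mc = list(n_photons = 3e5), seed = 11)
ds    <- simulate_dataset(cfg)            # ~4 min: 10 transport runs, 2250 samples
split <- random_split(ds$epr, seed = 11)  # 80/20 within each depth
cmp   <- run_comparison(ds$epr, ds$ror, split, train_config(seed = 11))
cmp$metrics
#> # A tibble: 2 × 4
#>   type    mae   std     r
#> 1 epr    8.27  8.84 0.726
#> 2 ror   12.9   9.02 0.453
```

EPR features beat the RoR baseline on both error and correlation at this
desk scale; the improvement column of `cmp$improvement` reports the margin
in percent. A thin command-line wrapper over the same functions lives at
`inst/cli/tfo.R` (subcommands `simulate`, `features`, `ppg-synth`,
`ppg-extract`, `train`, `compare`).

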