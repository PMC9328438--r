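# fflux

Fluorescence fluctuation spectroscopy — forward simulation and analysis —
for single-molecule studies of membrane receptor organization.

## The problem

Fluorescence correlation spectroscopy (FCS) and photon counting histogram
(PCH) analysis quantify, from photon-count fluctuations in a femtoliter
confocal volume parked on a living cell's plasma membrane, three properties
of a fluorescently tagged receptor population:

* the **particle density** N/μm² — from the autocorrelation amplitude,
  G(0⁺) = 1/N, over the calibrated beam area A = πω²;
* the **diffusion coefficient** D = ω²/(4 τ_D) — from the autocorrelation
  decay time τ_D and the beam waist ω, itself calibrated against a dye of
  known D via ω = √(4 τ_D,cal · D_ref);
* the **molecular brightness** ε (counts·molecule⁻¹·s⁻¹) — from the
  super-Poissonian shape of the photon counting histogram, reporting
  receptor clustering and oligomerization.

The autocorrelation models are the standard multi-component forms
G(τ) = (1/N)·(1 + T/(1−T)·e^(−τ/τ_tr)) · Σᵢ fᵢ·gᵢ(τ) with
g₂D = (1+τ/τ_Dᵢ)⁻¹ and g₃D = (1+τ/τ_Dᵢ)⁻¹(1+τ/(S²τ_Dᵢ))^(−1/2):
a single 3D component for dye calibration, two 2D components plus a
photophysics term for membrane receptors and receptor–arrestin (BiFC)
complexes, and a fixed-τ_D1 3D component plus two 2D components for
fluorescent-ligand binding.  Concentration-response data are fitted with
Response = Emax·A/(A + EC₅₀).

fflux provides, as one tested toolchain:

* a Brownian-dynamics **photon-trace simulator** (3D-Gaussian detection
  volume, 2D membrane and 3D solution species, telegraph dark-state
  kinetics, Poisson photon statistics, seeded and bit-reproducible);
* a **multi-tau correlator** (16 lags/octave, ×2 rebinning, symmetric
  normalization) plus a brute-force oracle correlator;
* **model fitting** for all three ACF models with beam-waist calibration
  and conversion to D and N/μm²;
* **PCH analysis** — exact compound-Poisson model evaluation, one- and
  two-component brightness fits, first-order out-of-focus correction,
  F-test model selection;
* **Emax fitting** with profiled pEC₅₀ and a no-response test;
* an **experiment pipeline** from calibration to condition-level
  mean ± SEM tables, fully reproducible from one seed.

## Worked example

Simulate a 30 s membrane read at published vehicle-condition ground truths
(density 36.7 /μm², D 0.13 μm²/s, ε 18111 cps), then recover diffusion and
density:

```r
library(fflux)
vol <- detectionVolume(omega = 0.2, S = 5)
receptor <- speciesSpec("2D", D = 0.13, density = 36.7, epsilon = 18111)
cfg <- simulationConfig(vol, receptor, duration = 30, binTime = 1e-4,
                        dt = 1e-4, boxScale = 5, seed = 42)
trace <- simulateTrace(cfg)
trace
#> PhotonTrace: 300000 bins of 0.0001 s (30 s total), mean rate 4.402e+04 counts/s

curve <- autocorrelate(trace)
curve
#> CorrelationCurve: 224 lags from 0.0001 to 13.1 s, G(first lag) = 0.2012

fit <- fitMembraneACF(curve, vol)
fit
#> ACFFit (membrane model): N = 3.824, T = 0.05, tauTr = 4e-06 s, chisq = 0.03204
#>  kind       tauD  fraction fixed
#>    2D 0.07584958 0.7388995 FALSE
#>    2D 1.41517671 0.2611005 FALSE

dom <- dominantComponent(fit)
sprintf("D = %.3f um^2/s, density = %.1f /um^2",
        deriveDiffusion(dom$tauD, vol), deriveDensity(fit, vol))
#> "D = 0.132 um^2/s, density = 30.4 /um^2"
```

The zero-lag amplitude 0.20 reads N ≈ 4 particles in the beam area
(0.126 μm²); the dominant dwell time 76 ms converts to D = 0.132 μm²/s
against the 0.13 ground truth, and the amplitude-derived density lands near
the generating 36.7 /μm² (single reads scatter ±20–30%; condition summaries
in `runExperiment()` average over cells).

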