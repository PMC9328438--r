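---
title: "Simulating and analysing membrane-receptor fluorescence fluctuations with fflux"
author: "fflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing membrane-receptor fluorescence fluctuations with fflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflux)
```

## The measurement this package models

Fluorescence correlation spectroscopy (FCS) parks a diffraction-limited
confocal volume on a sample — here, the upper plasma membrane of a live cell
expressing a GFP-tagged G protein-coupled receptor — and records the photon
count rate in microsecond bins.  Receptors diffusing through the ~0.1 um^2
illuminated membrane area produce intensity fluctuations whose
autocorrelation G(tau) encodes two numbers per measurement: the mean number
N of fluorescent particles in the detection area (the inverse of the
zero-lag amplitude) and their average dwell time tau_D (the decay time).
With a calibrated beam waist omega these become a particle density N/um^2
and a diffusion coefficient D = omega^2 / (4 tau_D).  The photon counting
histogram (PCH) of the same trace adds a third, complementary number: the
molecular brightness epsilon (counts per molecule per second), which
reports oligomerization — two receptors moving as one complex are half as
many particles at twice the brightness.

fflux implements this entire workflow twice over: a forward Brownian-dynamics
simulator that generates photon traces with known ground truth, and the
analysis chain (multi-tau correlation, diffusion-model fitting, calibration,
PCH fitting, Emax concentration-response fitting) that recovers those truths.
Closing that loop is the package's acceptance standard: every analysis
stage is validated against either exact oracles or parameter recovery from
its own generative model.

## The forward model

`simulateTrace()` propagates point emitters in a periodic box:

* **Geometry.** The detection volume is a 3D Gaussian,
  MDF(r) = exp(-2 (x^2+y^2)/omega^2 - 2 z^2/(S omega)^2), with lateral
  1/e^2 waist omega (um) and structure parameter S (axial elongation).
  Membrane ("2D") species are confined to the focal plane z = 0; solution
  ("3D") species fill the box.  The box has lateral half-width
  `boxScale * omega` (default 8, floor 5) and axial half-width 2.5 S omega;
  both choices keep re-entry artifacts of the periodic wrap far below the
  fitted decays while keeping particle counts tractable.
* **Dynamics.** Per step of length `dt`, each coordinate receives a Gaussian
  increment of standard deviation sqrt(2 D dt).  Dark-state (triplet or
  GFP-blinking) kinetics are a two-state telegraph process parameterized by
  the stationary dark fraction T and the relaxation time tau_dark; the
  discrete-time transition probabilities are the exact two-state
  matrix-exponential sampling, so the stationary occupancy is T for any dt.
  The simulator refuses dt > tau_dark/5.
* **Photons.** Each bin's count is one Poisson draw whose mean accumulates
  `epsilon * MDF` over all bright particles and steps, plus background.
  Particle numbers per species are Poisson with mean density x box measure
  (grand-canonical), so occupancy fluctuations in the detection region are
  Poissonian, as the FCS and PCH models assume.
* **Determinism.** All randomness flows through R's RNG under a local seed;
  a `SimulationConfig` maps to a bit-identical trace, and the caller's RNG
  state is untouched.

Default acquisition settings mirror standard practice: 30 s reads, raw bins
of 2 us (rebinnable downstream), dt = 1 us.  Membrane recovery studies in
the tests and the acceptance script simulate directly at the 100 us
analysis bin time with dt = binTime, which is accurate because membrane
dwell times (tens of milliseconds) dwarf the bin: the per-bin displacement
is ~omega/40.  Laser power, photobleaching and detector artifacts are not
modeled; epsilon is an effective detected per-molecule count rate.

What the generator deliberately does *not* emulate about real data:
cell-to-cell expression variability, membrane curvature and compartment
corrals, photobleaching during the read, and detector afterpulsing or dead
time.  Passing recovery tests therefore demonstrate the self-consistency and
calibration of the estimators under the stated model, not robustness to
every artifact of live-cell measurements.

## Correlation

`autocorrelate()` is a classic multi-tau correlator: m = 16 linear lags per
octave, counts rebinned x2 per octave — the scheme of hardware correlators.
G is normalized so G(inf) = 0 and the zero-lag amplitude reads 1/N.  Two
normalizations are available: *symmetric* (default; separate means for the
leading and lagging segments at every lag, removing the long-lag
normalization bias of progressive rebinning) and *global* (the textbook
single-mean definition).  `autocorrelateDirect()` evaluates the definition
literally at every integer lag in O(N x lags) and is the package's internal
oracle: at base resolution the two estimators are mathematically identical
and the tests require agreement to 1e-12.  For rebinned octaves the
multi-tau value estimates a triangularly lag-averaged covariance, which is
not the native-lag covariance; there the oracle equivalence asserted is
against the direct estimator applied to the identically rebinned series,
which is again an identity.

Repeated reads of one cell are correlated separately and the curves averaged
with per-lag `npts` weights (`averageCurves()`), rather than concatenating
counts; this mirrors instrument behaviour and avoids a spurious correlation
step at the read boundary.

## Fitting the diffusion models

`acfModel()` evaluates
G(tau) = (1/N) (1 + T/(1-T) exp(-tau/tau_tr)) sum_i f_i g_i(tau) with
g_2D = (1 + tau/tau_Di)^-1 and
g_3D = (1 + tau/tau_Di)^-1 (1 + tau/(S^2 tau_Di))^-1/2.  Three fit
front-ends share one engine:

* `fitCalibration()` — one 3D component plus triplet, for dye standards of
  known D; omega = sqrt(4 tau_D D_ref) and A = pi omega^2 follow.  S is
  fitted within [3, 10].
* `fitMembraneACF()` — two 2D components plus a photophysics term, S fixed
  to the calibration value (receptor-GFP and BiFC receptor–arrestin data).
* `fitLigandACF()` — fixed-dwell-time 3D component (free fluorescent
  ligand, calibrated in buffer) plus two free 2D components (bound ligand);
  binding is represented by the slowest component.

Numerical choices that matter:

* **Optimizer.** Bounded Levenberg–Marquardt (minpack.lm) from five
  deterministically jittered starts; lowest residual sum wins, so results
  are independent of start order.  Box bounds are imposed through the
  smooth sine transform p = lo + (hi-lo)(sin z + 1)/2 rather than
  clamping — clamped LM trajectories can wedge into bound corners (we saw
  exactly this with the triplet-time bound), while the transform keeps the
  problem smooth and lets noiseless roundtrips converge to ~1e-8 relative.
* **Weights.** Residuals are weighted by sqrt(npts) from the correlator;
  the per-lag standard error is taken to scale as 1/sqrt(number of averaged
  lag products).  Nothing else is known about the error structure, and this
  choice keeps the heavily averaged short lags in charge of the amplitude.
* **Fit window.** 4 us to 1 s by default: below 4 us real instruments are
  afterpulsing-dominated (not modeled), beyond 1 s a 30 s trace averages
  too few products.
* **Baseline.** The cell models fit a small free baseline (bounded to
  +/- 30% of the amplitude guess).  A finite trace of duration T biases the
  normalized ACF by roughly -(2/T) Int G dtau because the mean is estimated
  from the same trace; for slowly decaying 2D membrane correlations
  (tau_D ~ 0.1 s) this reaches several percent of the amplitude and, left
  uncorrected, shortens fitted dwell times by ~10%.  The baseline converges
  to zero on noiseless curves, so roundtrips are unaffected.  Calibration
  fits of fast dyes (tau_D ~ 30 us) do not need it and stay baseline-free.
* **Ordering and degeneracy.** The two 2D dwell times are parameterized as
  tau_D2 and a ratio >= 1, so components come back sorted.  A fitted ratio
  below 2 flags the fit as degenerate and triggers a single-2D refit — with
  a single underlying species this is the expected, correct outcome.  2D
  dwell times are bounded below at 100 us: faster "membrane" components are
  physically meaningless and would otherwise absorb free-dye or triplet
  decay in ligand fits.
* **Triplet bound.** tau_tr < 50 us keeps the photophysics term from eating
  diffusion decay.  For dyes with tau_D ~ 30 us the triplet, dwell time and
  S still trade off on a flattish likelihood ridge; single short
  calibration reads can land ~20% off in omega, which is why calibration
  closure is judged on the median of repeated reads.

Derived quantities follow the instrument conventions: D = omega^2/(4 tau_D)
(`deriveDiffusion`), and density = f N / A (`deriveDensity`) where f is the
summed 2D amplitude fraction for membrane/BiFC fits and the slowest-component
fraction for ligand fits.  "Fractional contribution" is implemented as
amplitude fraction.  With the 2D in-plane reference area A = pi omega^2, the
fitted N of a single membrane species equals density x A exactly, so the
density closes on the generator's ground truth with no gamma-factor
correction.

## Photon counting histograms

`computePCH()` rebins (by summation) and tallies counts.  `pchModel()`
computes the count distribution for a mixture of species from first
principles: the single-particle probabilities p1(k) are numerical integrals
of the Poisson distribution over the MDF amplitude distribution (a smooth
one-dimensional integral after a change of variables; 320-point
Gauss–Legendre), and the particle-number average is evaluated exactly by the
compound-Poisson (Panjer) recursion over the combined jump intensity
nu(j) = sum_i Nbar_i p1_i(j).  Reference volumes are the 1/e^2 effective
volumes — V_ref = pi^{3/2} omega^2 (S omega) for the 3D Gaussian (gamma
factor 2^{-3/2}) and A_ref = pi omega^2 for the 2D in-plane MDF (gamma
1/2) — so PCH particle numbers share the scale of the FCS amplitude N, and
the modeled mean per bin is gamma_1 sum_i epsilon_i Nbar_i binTime
(asserted to 1e-6 in the tests).

The first-order out-of-focus correction F adds F gamma_1 epsilon Nbar
binTime to the single-photon (k = 1) jump intensity: to first order in the
local excitation, emission from the large, weak out-of-focus volume only
ever contributes single photons.  (A pure "rescale the reference volume by
1+F" formulation cancels identically in the compound-Poisson jump intensity
and would leave F unidentifiable, so the k = 1 form — the standard
first-order correction — is what is implemented; the choice is recorded in
the JSON fit reports.)  `calibratePCHCorrection()` freezes F from a
one-component fit of a calibration-dye histogram at 20 us bins with F free,
the protocol's convention; fits reject F > 5 as a bad calibration.  In the
simulator's exactly Gaussian volume the true F is 0, and the quasi-static
closure test recovers |F| < 0.1.  Fast dyes at 20 us bins violate the PCH
snapshot assumption (rms motion ~ omega/2 per bin), which the fit absorbs
partly into F and partly into epsilon; with adequate statistics (2 s
calibration reads) the frozen F stays below ~0.06 and perturbs downstream
brightnesses by at most that factor.

`fitPCH()` is a minimum chi-square fit (expected-frequency weights) with
one or two components, brightness parameterized as epsilon_1 and a ratio
>= 1 (sorted output; ratio < 2 flags a collapsed two-component fit), over
counts 0..k_obs+10.  `selectPCHModel()` chooses the component count by an
F-test at alpha = 0.01 — the protocol's "preferential" fit made concrete —
with a parsimony guard: a collapsed two-component fit never wins.  For
membrane traces the 2D in-plane MDF variant (`geometry = "2d"`) matches the
generative geometry and is used in the recovery studies; the 3D-Gaussian
default mirrors uniform instrument protocols.  Residual brightness bias on
30 s membrane traces is about -5 to -9%: a slow membrane trace holds only
~400 statistically independent occupancy snapshots, so the histogram noise
is far from multinomial and the minimum-chi-square estimator pays a small
finite-sample bias.  This is documented rather than corrected; it sits well
inside the 20% recovery band.

## Concentration-response fitting

`fitEmax()` fits Response = basal + Emax A/(A + EC50) with Hill slope fixed
at 1 (the protocol's equation has none).  At fixed pEC50 the model is linear
in (basal, Emax), so pEC50 is profiled: a 200-point scan two decades beyond
the data brackets the optimum and one-dimensional minimization polishes it
(tolerance 1e-10).  This is deterministic, immune to start choice, and
recovers noiseless potencies to < 1e-6 log units.  "No response" (NR) is
declared when an F-test cannot distinguish Emax from 0 at alpha = 0.05, or
when the data are exactly flat.  Both basal-fitting and basal-fixed variants
are exposed (`fitBasal`); the standard error of pEC50 comes from the local
quadratic of the profile RSS.

## The experiment pipeline

`runExperiment()` reproduces a full study from a configuration list (or YAML
file): it calibrates the detection volume from a simulated dye-standard
read and the PCH correction from the same trace, then simulates each cell
of each condition (two 30 s reads by default, correlated separately and
averaged), fits the condition's model with S fixed from calibration,
derives D, density and brightness per cell, and aggregates mean +/- SEM
with n per condition.  Per-cell failures are logged and excluded; a
calibration failure aborts.  Cell-level aggregation is used throughout (the
alternative, averaging per independent experiment first, is a documented
ambiguity of such summary tables).  Everything derives deterministically
from one base seed.

## Problem sizes used in validation

The test-suite and acceptance-script study conditions are the published
membrane ground truths (vehicle: density 36.7 /um^2, D 0.13 um^2/s,
epsilon 18111 cps; agonist-treated: 64.1, 0.09, 24027; receptor–arrestin
BiFC vehicle: total 7.9 /um^2, D 0.24, brightness populations 4383 and
34006 cps, split equally between the two populations in the absence of a
stated ratio).  Recovery runs use single 30 s reads at 100 us bins, 20
seeds per condition, a simulation box of half-width 5 omega, and median
statistics; pipeline plumbing tests use shorter reads and fewer cells.
The BiFC amplitude-derived density is intentionally *not* a recovery
quantity: with two brightness populations the FCS amplitude N is
brightness-squared weighted and reads ~0.63 of the true total at that
brightness ratio — a property of the method, reproduced faithfully.
Ligand-binding recovery simulates free ligand (D = 316 um^2/s, the 633 nm
channel standard) plus a bound membrane species at D = 0.15 um^2/s and a
representative bound density of 10 /um^2 (a mid-range surface density for
low-nanomolar fluorescent-agonist binding), and checks the
slowest-component D from the fixed-tau_D1 three-component fit.

## Known limitations

* The two-component membrane fit on single-species data occasionally splits
  the decay across both components; the dominant-component convention and
  median-over-seeds statistics absorb this, but individual cells can be
  ~30% off in D.
* Brightness estimates from slow membrane traces carry the few-percent
  finite-sample bias discussed above.
* The PCH model assumes static snapshots; histograms of fast solution dyes
  at long bin times are motion-blurred and push bias into F and epsilon.
  The package follows the protocol (20 us calibration bins) and documents
  the consequence rather than modeling intra-bin diffusion.
* No photobleaching, afterpulsing, background structure or expression
  variability; see the forward-model section.
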