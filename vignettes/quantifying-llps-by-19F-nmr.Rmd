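---
title: "Quantifying protein phase separation from probe-molecule 19F NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein phase separation from probe-molecule 19F NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorlps)
library(dplyr)
```

## The measurement principle

When a protein solution undergoes liquid–liquid phase separation (LLPS), it
demixes into a protein-rich *dense* phase and a protein-poor *lean* phase. A
small fluorinated probe molecule such as trifluoroethanol (TFE), added at low
concentration, partitions freely between the phases, and its ¹⁹F chemical
shift reports the *local* protein concentration: in the linear regime the
shift obeys

$$\delta = \delta_0 + \theta_C\,C + \theta_T\,\Delta T + \theta_Y\,Y$$

with $\delta_0$ the shift of the free probe at the 25 °C reference
temperature, $C$ the protein concentration (mg/mL), $\Delta T$ the
temperature offset (°C) and $Y$ the concentration of an additive (mM, here
the trivalent salt that triggers LLPS). During phase separation the single
probe resonance splits into two overlapping Lorentzians — a narrow upfield
line from the lean phase and a broad downfield line from the dense phase
(for $\theta_C > 0$). Deconvolution then yields, per time point:

* phase **concentrations** from the fitted centres (inverting the
  calibration),
* phase **volumes** from the fitted areas,
  $V_P = (I_P / I_T)\, V_O$, where $V_O$ is the NMR-observed volume,
* phase **masses** $M_P = C_P V_P$, whose sum should equal the known total
  protein mass — a built-in conservation audit.

A second fluorinated compound (trifluorotoluene, TFT) sits in a coaxial
insert: its shift is concentration-insensitive, so its linewidth reports
macroscopic field homogeneity. When the dispersed phases settle into
macroscopic layers, susceptibility gradients broaden the reference line —
the onset of layer separation is read off that width series.

## Package shape

The package is tidyverse-native: spectra are tibbles (`ppm`, `intensity`)
with metadata attributes, every analysis step takes a data frame first and
returns a tibble, fitted objects have `tidy()`/`glance()` methods and each
result type has an `autoplot()` method. The module layout follows the
processing chain: I/O and FID processing, Lorentzian deconvolution,
calibration/quantification, relaxation and diffusion models, slice analysis,
kinetics, simulation, and pipeline orchestration.

## Deconvolution

`fit_lorentzians()` minimizes the residual of one or two area-parameterized
Lorentzians plus a constant baseline by Levenberg–Marquardt. Choices that
matter:

* **Area parameterization.** Integrals are the observable that enters the
  volume formula, so the area is a fit parameter rather than derived from
  height × width.
* **Bounds.** FWHM ∈ [0.1, 5000] Hz, areas ≥ 0, centres inside the axis.
  Non-convergence triggers jittered restarts and is always reported through
  a `converged` flag.
* **Model selection.** `select_n_components()` returns 2 only when the
  two-component fit improves BIC by more than 10 *and* both areas exceed 2%
  of the total. The experiment does not define when one peak "becomes" two;
  this conservative rule avoids spurious splitting before the onset of
  phase separation. Near-zero residuals are floored at the data's double
  precision so that two numerically perfect fits compare as equal.
* **Warm starts.** In kinetic series each fit is seeded from the previous
  time point's solution; bounds and selection criteria are unchanged, so
  each spectrum is still fit independently.
* **Probe window.** Fits are restricted to a ±1.5 ppm window around the
  probe resonance (−77 ppm) to exclude the reference line.

Confidence intervals come from `monte_carlo_ci()`: the residual noise level
is estimated from the fit, `n_reps` synthetic replicates (model + Gaussian
noise) are refitted, and the 2.5/97.5 percentiles of each parameter are the
95% interval. Nested simulation in the test suite confirms ~95% empirical
coverage of the centre parameter at SNR 100.

## Calibration and uncertainty

`fit_calibration()` is ordinary least squares on the linear shift model; the
inversion `shift_to_concentration()` propagates both the shift uncertainty
and the coefficient covariance to first order (delta method). Negative
inverted concentrations are floored at zero for downstream use but the
unfloored value is kept for auditing. The packaged default coefficients
(δ₀ = −77.000 ppm, θ_C = +0.0025 ppm per mg/mL, θ_T = +0.010 ppm/°C,
θ_Y = −0.005 ppm/mM) are **synthetic fixtures** — real coefficient tables
are instrument- and system-specific and must be supplied by the user; the
fixture signs put the dense phase downfield of the lean phase, matching the
observed ordering.

## Biophysical reference models

Three closed-form models provide the "expected" curves against which probe
behaviour is compared:

* Temperature scaling of transverse relaxation,
  $R_2^T = R_2^{\mathrm{ref}}\,\eta_T T_{\mathrm{ref}} / (\eta_{\mathrm{ref}} T)$,
  from the Stokes–Einstein–Debye proportionality of $R_2$ to the rotational
  correlation time (the effective radius cancels).
* The rearranged Stokes–Einstein scaling of diffusion,
  $D^T = D^{\mathrm{ref}}\,\eta_{\mathrm{ref}} T / (\eta_T T_{\mathrm{ref}})$ —
  the exact reciprocal of the former, asserted as an identity in the tests.
* Crowding-limited diffusion
  $D(\varphi) = D^{\mathrm{diluted}} (1-\varphi)^3 / (1 + \tfrac32\varphi + 2\varphi^2 + 3\varphi^3)$
  with $\varphi$ from the concentration and a specific volume of
  0.735 mL/g. At the isolated-fraction concentrations the factor evaluates
  to ≈ 0.250 (360 mg/mL) and ≈ 0.761 (80 mg/mL).

Water viscosity uses a Vogel-type correlation
($\eta = 2.414\times10^{-5}\,\mathrm{Pa\,s} \times 10^{247.8/(T-140)}$,
$T$ in K), which matches tabulated values within ~0.3% across 0–100 °C; the
correlation is an argument (`viscosity_fn`) so another can be substituted.
Decay fitting (inversion recovery, CPMG, Stejskal–Tanner with the ¹⁹F
gyromagnetic ratio γ/2π = 40.078 MHz/T) shares the Monte-Carlo CI engine.

## Slice geometry and settling

Selective excitation of bandwidth $bw$ during a z-gradient $G$ excites a
slice of width $bw/(\gamma G)$ centred at $f/(\gamma G)$ for pulse offset
$f$. The defaults (42.4 G/cm, 16793 Hz, twelve offsets spanning ±93404 Hz)
give ≈ 0.99 mm slices centred at −5.5 … +5.5 mm. Gradient nonlinearity is
corrected by scaling each slice with (mean reference integral)/(slice
reference integral) — idempotent, and exact for a homogeneous sample.

The dense/lean boundary is defined as the height where the dense volume
fraction crosses 50%, linearly interpolated between slice centres; the
experiment describes boundary motion only qualitatively, so the 50% rule is
this package's operational definition. Settling is summarized by a
two-segment piecewise-linear fit with the breakpoint chosen by exhaustive
search (O(n) via running sums), and the layer-separation onset is the first
time the reference half-width exceeds its baseline median by 20% for three
consecutive points — threshold and persistence are arguments.

## The synthetic-data generator

No public instrument data exist for this experiment, so the generator is a
first-class module: every pipeline stage is tested against trajectories with
known ground truth. It implements the staged phenomenology of a
temperature-jump LLPS:

* dense concentration
  $C_d(s) = C_{\min} + (C_{\mathrm{init}}-C_{\min})e^{-s/\tau_1} + (C_{\mathrm{final}}-C_{\min})(1-e^{-s/\tau_2})$
  with $s = (t-\mathrm{lag})_+$ and $\tau_1<\tau_2$, whose analytic minimum
  is the crossover;
* dense volume rising as a saturating exponential to its peak at the
  crossover, then relaxing toward the volume implied by the target final
  concentrations;
* lean concentration from **exact mass conservation**,
  $C_l = (M_{\mathrm{total}} - C_d V_d)/(V_O - V_d)$;
* an arrested mode that freezes the volume at its maximum (gel-like
  network) with continued slow densification and no settling.

The functional forms are package inventions that realize the staged
narrative; all parameters are exposed. Defaults anchor to the printed
experimental facts: 200 mg/mL total protein in a 236.8 µL observed volume
(47.36 mg expected total mass), isolated-fraction concentrations 360/80
mg/mL as the dense/lean final targets, settling onset 140 min, boundary
rates 0.154 then 0.004 mm/hr with the regime change at 1100 min. Preset
kinetic constants (lag, τ₁, τ₂) are chosen so the presets reproduce the
qualitative orderings: the 40 °C jump has a pronounced lag and a crossover
near the end of a 120 min window, 45 °C crosses over near 40 min, and
50 °C arrests. Remaining constants (probe linewidths 15/80 Hz for
lean/dense, reference width 3 Hz, inhomogeneity broadening saturating at
6 Hz) are plausible values for a cryoprobe ¹⁹F instrument, chosen once.

Noise is i.i.d. Gaussian in the frequency domain (thermal noise after FT),
with the **SNR defined on the tallest probe peak** — the signal that is
actually deconvoluted — not on the much taller, narrow reference line; this
keeps the generator's SNR consistent with the SNR definition used in the
deconvolution recovery analyses. Spectra are rendered at 32768 points over
30 ppm, which resolves 5 Hz features at 470 MHz.

What the generator does *not* emulate: baseline and phase distortions,
temperature-dependent linewidth schedules beyond linear interpolation,
droplet-scale physics (nucleation, coalescence, size distributions), radiation
damping, or field drift. Passing tests therefore demonstrate correctness of
the estimators under the stated noise model, not robustness to every
instrumental artefact of real data.

## Problem sizes and numerical choices

Simulation-based tests run at the default study conditions: 0.5 min
sampling over 120 min (241 spectra) for bulk kinetics at SNR 100; nested
Monte-Carlo coverage at 200 outer × 200 inner replicates on 256-point
probe windows; settling recovery on 1 min boundary sampling over
150–4000 min with 0.05 mm position noise (following the layer evolution
over roughly three days, consistent with the days-long timescale of dense
layer compaction). Crossover detection uses a 5-sample centred moving
average (2.5 min at the default sampling); with the default presets the
concentration dip is shallow, and the detected crossover scatters by a few
minutes around the analytic value at SNR 100 — the volume-maximum
cross-check and discordance flag exist for exactly this reason. The
two-segment settling fit floors segment SSE at zero against floating-point
cancellation; degenerate (single-slope) data return equal rates for both
regimes.

## Known limitations

* Only absorptive real spectra are handled; phase and baseline correction
  are assumed done upstream (a constant baseline term is the only
  concession).
* At most two Lorentzian components; Voigt/Gaussian lineshapes are out of
  scope.
* The calibration is strictly linear — valid in the dilute-probe regime the
  experiment operates in, not near binding saturation.
* The slow settling rate (0.004 mm/hr) is tiny against realistic boundary
  noise; resolving it within a few percent requires long, densely sampled
  trajectories (the study conditions above), and the anomalous temperature
  dependence of dense-phase relaxation (chemical exchange) is deliberately
  not modelled.
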