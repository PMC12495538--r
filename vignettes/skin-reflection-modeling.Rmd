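---
title: "Modeling millimeter-wave reflection of human skin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling millimeter-wave reflection of human skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinwave)
```

## The problem

Compliance testing of wireless devices above 6 GHz is formulated in terms of
the absorbed power density (APD) at the body surface. Demonstrating
compliance requires dielectric skin models that *conservatively* reproduce
how much of an incident millimeter-wave field the skin absorbs. The dominant
physics is an impedance-matching effect in the stratum corneum (SC): a thin
(~20 µm) low-permittivity layer on most of the body, but a thick
(~200–300 µm) layer on the palms and inner fingers, where it acts as a
matching layer that increases absorption above roughly 20 GHz.

`skinwave` implements the complete modeling chain around this problem:

1. **Dispersion** — single-pole Cole–Cole / Debye complex permittivity.
2. **Layered media** — analytic plane-wave reflection of a stratified lossy
   stack, and its spectral-domain generalization.
3. **Waveguide probe** — a mode-matching (MM) forward model of the
   open-ended rectangular waveguide probes used to measure skin reflection
   in vivo.
4. **Fitting** — bounded least-squares extraction of layer parameters from
   dB reflection spectra.
5. **Statistics** — the dB-domain pipeline that turns cohort measurements
   into population-coverage skin models.
6. **Synthetic data** — a seeded cohort generator so the entire pipeline is
   testable although the underlying volunteer data are not public.

## Dielectric model

Each material is described by

$$\epsilon_r(\omega) = \epsilon_{r\infty}
  + \frac{\epsilon_{rs} - \epsilon_{r\infty}}{1 + (j\omega\tau)^{1-\alpha}}
  - \frac{j\sigma}{\epsilon_0\omega},$$

with $\alpha = 0$ the Debye special case. All solvers share one constants
table (CODATA 2018) and one time convention, $e^{+j\omega t}$, under which
passive media have $\mathrm{Im}\,\epsilon_r \le 0$. The fractional power
uses the principal branch; $\omega\tau > 0$ keeps the argument away from the
branch cut. The shipped registry (`skin_registry()`) carries the validation
gel, the PTFE coatings, and the fitted skin models: the inner-skin layer
("Layer D") for the population mean and for the 68%/95% coverage factors,
the thin SC (literature parameters, fixed at 20 µm), and three thick-SC
models at 227/262/295 µm. File units follow the table conventions
(micrometers, picoseconds); conversion to SI happens at exactly one
boundary, the registry loader.

`fit_debye_to_dispersion()` produces per-band Debye surrogates of a
Cole–Cole material by least squares on complex permittivity, sampled on a
logarithmic 50-point grid with equal real/imaginary weight. Over the 21–42
GHz band the surrogate of the validation gel stays within 0.6% of the
Cole–Cole original.

## Plane-wave reflection of a stratified stack

`plane_wave_reflection()` uses recursive impedance transformation: each
layer contributes its wave admittance $Y = k_z/(\omega\mu_0)$ (TE) or
$\omega\epsilon_0\epsilon_r/k_z$ (TM) with
$k_z = \sqrt{k^2 - k_t^2}$ on the branch $\mathrm{Im}\,k_z \le 0$, and the
recursion uses the numerically stable $\tanh$ form so that arbitrarily
thick lossy layers cannot overflow. The reflection coefficient is defined so
that a vacuum/half-space interface at normal incidence returns the Fresnel
value $(1-\sqrt{\epsilon_r})/(1+\sqrt{\epsilon_r})$; TE and TM coincide at
normal incidence. The implementation is cross-validated in the test suite
against an independently coded 2×2 transfer-matrix oracle on random lossy
stacks to better than $10^{-10}$ relative.

All headline reflectance numbers are reported at **normal incidence**. The
underlying study does not state an incidence angle for its plane-wave
curves; normal incidence is the standard choice for APD compliance surfaces,
and the solver retains oblique angles and both polarizations for
sensitivity work.

## The waveguide probe forward model

The measured quantity is the TE₁₀ reflection coefficient of an open-ended
rectangular waveguide pressed against the skin, referenced at the
flange/sample plane. `te10_reflection()` implements a mode-matching model
under the infinite-flange assumption:

* the aperture field is expanded in the guide's TE/TM mode basis (modes of
  the parity that couples to TE₁₀: $m$ odd, $n$ even);
* the exterior field is a two-dimensional spectrum of TE/TM plane waves,
  each weighted by the layered-medium input admittance
  (`stack_admittance()`) at that transverse wavenumber — this is where the
  fringing fields that spill past the aperture are captured;
* continuity of the tangential fields over the aperture is enforced by
  Galerkin projection, giving a dense linear system whose TE₁₀ solution
  coefficient yields S₁₁.

The aperture-mode Fourier transforms are closed forms, evaluated with
removable-singularity-safe expressions, so the spectral integrand is cheap
and exact; quadrature is polar, with angular Gauss–Legendre nodes replicated
over the four quadrants (making parity cancellations exact to rounding) and
radial panels that resolve the propagating region $[0, 3k_0]$ and then
extend geometrically to the truncation radius
$\max(30\,k_0,\ 3\,k_{c,\max})$, which always covers the most evanescent
retained mode.

**Numerical defaults were frozen by self-convergence, not by matching any
external code**: with 48 retained modes, 12 angular points per quadrant and
32+16-point radial panels, doubling every count moves the gel and skin
fixtures by less than 0.05 dB everywhere in the WR42/WR28 bands (the
dominant error is mode truncation, which converges slowly because of the
aperture-edge field singularity). The ideal short ($S_{11}=-1$) is
reproduced to $4\times10^{-5}$ by a metal-like termination, and a dedicated
`short = TRUE` flag returns the calibration value exactly.

Probe geometries are the EIA standard inner dimensions for WR42, WR28,
WR15 and WR10. The published usable bands quote edges (14 and 21 GHz) that
lie marginally *below* the TE₁₀ cutoffs implied by those dimensions
(14.05 and 21.08 GHz); the registry therefore stores 15–28 GHz (WR42) and
21.5–42 GHz (WR28), and the solver refuses below-cutoff evaluations rather
than extrapolating. The 4.8 mm foam insert used in the hardware was included
in the instrument calibration, so it is *not* part of the default stacks; a
foam material is shipped for sensitivity studies.

The single-mode "transverse-resonance" approximation
(`te10_transverse_resonance()`), which ignores aperture coupling, differs
from the MM solution by 0.3–0.8 dB on the PTFE-coated gel across the WR28
band — the fringing-field contribution is not negligible for
low-permittivity cover layers, which is why the MM model exists.

## Parameter extraction

`fit_layer_d()` and `fit_sc_thick()` minimize the summed squared deviation
of **dB magnitude** between the forward model and the target over all
frequency points of all bands, equally weighted. dB magnitude (not complex
S₁₁) is the fitted quantity because the population statistics and coverage
curves are dB-magnitude objects and no phase means are reported for the
cohort. The optimizer is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with eight seeded multi-starts; the ordering
constraint $\epsilon_{rs} > \epsilon_{r\infty}$ is enforced by
reparameterizing with $\Delta\epsilon = \epsilon_{rs} - \epsilon_{r\infty}
\ge 0$, so every constraint is a box. Bound-pinned optima are flagged in
`bounds_active`; infeasible bounds raise an error before any optimization.

Noise-free self-consistency holds to machine precision: each shipped
parameter set, regenerated as a forward-model target, is recovered with
worst-case residual below $10^{-3}$ dB (typically far below), and the
thick-SC thicknesses 227 and 295 µm are recovered to better than 0.01 µm. A `forward = "planewave"` toggle lets large simulation studies and
the recovery harness use the fast analytic solver; production fits use the
MM model that matches the measurement.

Identifiability caveat: the four Debye parameters are not equally stiff
given dB-magnitude data over 15–42 GHz. A coherent whole-curve shift of a
few hundredths of a dB moves $\epsilon_{rs}$ by several percent while
changing the curve shape imperceptibly. Parameter-level closure statements
therefore quote noise-determined tolerances computed by a recovery harness
at the relevant noise level, while curve-level closure is the primary
criterion.

## Statistical pipeline

All statistics operate in dB ("log-normal" reflection magnitude). The
aggregation order is fixed by the measurement protocol: mean of the three
repeats, then averaging the sites within a subject's thin/thick class, then
cross-subject mean and SD per frequency. The tests are the standard base-R
implementations — Shapiro–Wilk for dB-normality, two-sided paired *t* for
the thin-vs-thick contrast, pooled two-sample *t* plus Bartlett for
demographic comparisons after `normalize_by_frequency_mean()` removes the
common frequency trend. No multiple-testing correction is applied,
mirroring the per-frequency reporting convention of the field. Coverage
curves are `mean − k·SD`, labeled "68%" (k = 1) and "95%" (k = 2) following
the convention used for coverage skin models; note these labels differ from
one-sided normal coverage (84.1% and 97.7%) — the package reproduces the
labels without reinterpreting them.

## The synthetic cohort generator

The generator emulates the study conditions: 44 subjects in the published
age/sex strata, seven thin-SC and ten thick-SC sites, three repeats, WR42
and WR28 analysis frequencies. Its defaults are fixed once, from study-level
anchors, and are not tuning knobs:

* **Thin-SC spread.** One standard normal draw per subject scales an SD
  curve rising linearly from 0.15 dB at 15 GHz to 0.5 dB at 110 GHz — the
  spread implied by the separation between the mean and the 1σ/2σ coverage
  models (0.3 dB at 15 GHz, 1.0 dB at 110 GHz for 2σ). Because the draw is
  shared across frequencies, per-frequency normality tests on the same
  cohort are strongly correlated, as they are in real repeated spectra.
* **Thick-SC mixture.** Per-subject SC thickness is lognormal with median
  210 µm (SD log 0.10) for the base (office-worker) population; a
  manual-labor fraction of 0.25 (11 of 44, the study's own proportion)
  multiplies thickness by a lognormal factor with median 1.8 (SD log 0.25),
  representing occupational callus while staying within the 50–600 µm range
  the fitting bounds assume. The thickness acts through the forward model of
  the thick-SC stack, producing the characteristic non-normal, low-side-
  outlier dB distributions: over 200 seeded cohorts, thick-SC samples fail
  Shapiro–Wilk (p < 0.01) at rate ≥ 0.99 at every WR28 analysis frequency,
  and essentially every cohort shows at least one subject more than 0.5 dB
  below the normal-quantile line.
* **Noise floors.** Site-level jitter 0.05 dB, repeat noise 0.05 dB,
  optional elderly offset (≤ 0.2 dB) disabled by default.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: anatomically resolved site differences beyond the
thin/thick dichotomy, instrument drift or calibration error, co-variation
of the thick-SC dielectric parameters with thickness, and the full
low-frequency variance inflation of real palms: with a fixed thick-SC
dielectric family, the thickness mixture under-disperses the 17.5 GHz
distribution (normality rejection rate ~0.9 there versus ≥ 0.99 in the
WR28 band) while over-dispersing the top of the WR28 band relative to the
reported 2–3× variance increase. Closure checks on thick-SC non-normality
are therefore stated in the WR28 band, and thin-SC normality at the WR42
frequencies.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full chain at desk scale,
a deliberate choice of problem size: 25 frequency points per band for
recovery fits, 5 frequencies per band for MM self-convergence, 200 cohorts
for closure rates, 1000 replicates for Shapiro–Wilk calibration, and
12-replicate recovery harnesses for noise-determined tolerances. Degenerate
inputs are rejected rather than patched: below-cutoff probe evaluations,
stacks without a terminal half-space, constant samples fed to the normality
test, missing repeats under the strict policy, infeasible fit bounds, and
non-monotone frequency grids all raise typed errors.

## Reproducing the pipeline end to end

```{r, eval = FALSE}
cfg <- cohort_config()
coh <- generate_cohort(cfg, seed = 77)
sm  <- summarize_cohort(coh$data)
thin <- sm[sm$sc_class == "thin", ]
fit <- fit_layer_d(
  fit_target(data.frame(probe = thin$probe, frequency = thin$frequency,
                        s11_db = thin$mean_db)),
  settings = fit_settings(forward = "planewave"))
fit$params
```

The recovered Layer D dispersion reproduces the generator's noise-free mean
curve to within a few hundredths of a dB (bounded by four standard errors
of the cohort mean at every frequency), which is the scaled-down analogue
of deriving the population skin model from the volunteer measurements.
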