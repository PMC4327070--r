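---
title: "Quantitative analysis of WGM microsphere biosensor spectra"
author: "wgmsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of WGM microsphere biosensor spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgmsense)
```

## The measurement this package models

A dye-doped polystyrene microsphere (diameter ~20 µm, n = 1.59) sitting on
the tip of a suspended-core optical fiber supports whispering-gallery modes
(WGMs): light trapped by total internal reflection circulating the sphere's
inner surface. The fluorescence of the embedded dye is modulated by these
modes, so the collected emission spectrum is a broad dye envelope carrying a
comb of narrow resonance peaks. When anything adsorbs onto the sphere --
polyelectrolyte layers, proteins binding to surface receptors -- the optical
path length grows and every resonance shifts to longer wavelength. Tracking
those shifts, at picometre precision, is the transduction principle.

Pumped hard enough, the sphere lases: above a threshold pump power the modes
inside the dye's gain window narrow dramatically (the Q factor jumps from
~3×10³ to ≥1.5×10⁴), which sharpens the resonance positions and improves the
detection limit. `wgmsense` implements the full analysis chain from raw
spectra to physical conclusions, plus a forward simulator so every inverse
step can be validated against known ground truth.

## The model chain

**Peaks and Q.** Resonances are detected by topographic prominence and fitted
with a Gaussian plus a local constant baseline (the dye envelope varies
slowly relative to a linewidth, so a local constant suffices). The quality
factor is the identity Q = λ/Δλ on the fitted centre and FWHM.

**Geometry.** Two successive first-order modes of the same polarization at
λ_m > λ_{m+1} give the mode number

  m = λ_{m+1}/(λ_m − λ_{m+1}) + 1

and the radius R = λ_{m+1}·m/(2π n_s): the round-trip optical path equals an
integer number of wavelengths. Both combs (TE and TM) interleave in the
spectrum; `pair_modes_fsr()` separates them by alternating assignment,
accepting the split only when it reduces the spacing variance at least
four-fold relative to the single-comb reading -- otherwise splitting a lone
comb would silently double the apparent FSR.

**Shift inversion.** A resonance shift maps to an effective radius increase
ΔR = R·Δλ/λ; a deposited layer of index n_L appears as Δλ/λ = n_L·e/(n_s·R),
so e = (Δλ/λ)·R·n_s/n_L. For adsorbed molecules the chain continues through
the Clausius–Mossotti polarizability

  α = (ε_r − 1)/(ε_r + 2) · 3Mε₀/(N_A ρ_m),   ε_r = n²,

the projected area per molecule σ_p⁻¹ = (n_s/n_L)·α/(ε₀(n_s²−n_m²)·δR), and
the surface mass density d = M/(N_A σ_p⁻¹). The bare α is used as a first
approximation to the excess polarizability; `molecule_properties()` records
that provenance and accepts a true excess value when one is available.

Two readings of the σ_p⁻¹ expression are dimensionally plausible regarding
where the index ratio sits; the implemented default (n_s/n_L multiplying,
δR dividing) is the one consistent with the effective-radius convention of
the thickness formula, and `eq5_variant = "nl_over_ns"` exposes the
alternative so the choice is auditable. The δR fed to this expression is
the plain R·Δλ/λ, *without* the n_L/n_s re-scaling -- that factor already
appears explicitly, and applying it twice would double-count the index
contrast. The reference λ anchoring the chain is the pre-shift resonance
centre; shifts are ≤10⁻³ of λ so this choice is second-order, but fixing it
makes results deterministic. The whole chain is homogeneous of degree 1 in
Δλ, so `density_shift_coefficient()` collapses it to one exact coefficient.

**Lasing threshold.** Peak intensity versus pump power is piecewise linear
with a kink at threshold. `fit_two_regime()` tries every split with ≥3
points per side, fits OLS lines to both sides, keeps the split with minimal
total SSE and intersects the two lines. The exhaustive search replaces a
by-eye choice of fitting regions. Gaussian *amplitude* is the default
"peak intensity"; peak area is an equally defensible convention and can be
computed from the fitted parameters (amplitude × fwhm × √(π/4ln2)).
Slopes equal within 10⁻⁶ of the intensity/power scale flag the fit
degenerate rather than producing a wild intersection.

**Kinetics and detection.** Shift series are converted to density series;
the plateau is the tail mean (robust, assumption-free) with an optional
single-exponential estimator `fit_saturation_exponential()` for simulated or
well-behaved data. The exponential model is linear in its amplitude, so the
amplitude is profiled out analytically and only log τ is searched -- a joint
two-parameter descent fails when τ is far below the sampling interval, where
the data constrain only the product behaviour. Detection uses a one-sided
3σ rule on the tail mean against the blank noise: conservative, auditable,
and with a 0.13 % false-positive rate under Gaussian blanks. Saturation is
declared when the tail slope is below 5 % of the plateau per record length
*or* statistically indistinguishable from zero (2 standard errors) --
without the second clause, point noise alone would veto saturation on
clearly flat tails.

**Electromagnetic sensitivity.** Resonance positions of the homogeneous
sphere come from the real-wavelength characteristic equation with
Riccati–Bessel functions ψ_l, χ_l (the dominant part of the Mie coefficient
denominators). TE modes (Mie b_l, tangential electric field) satisfy
ψ_l(mx)χ_l′(x) = m χ_l(x)ψ_l′(mx); TM modes (a_l, radial field component)
the index-swapped form. Roots are bracketed around an Airy-zero asymptotic
estimate and refined by Brent's method to residual ~10⁻¹⁰; a second,
independent Bessel implementation (plain downward/upward recurrences, no
shared code with the base Bessel routines) re-evaluates every root as a
cross-check. Bulk sensitivity dλ/dn_m is a central difference at
n_m ± 10⁻⁴ with the mode tracked by fixed (l, order, polarization) --
nearest-wavelength matching can slip a comb tooth across the difference.

A finding worth stating plainly: for R = 10 µm, n_s = 1.59, n_m = 1.33 near
620 nm this computation gives ≈16.3 nm/RIU for the first-order TE mode and
≈21.3 nm/RIU for TM, and a 5 µm/10 µm sensitivity ratio of ≈2.7 for both
polarizations. Literature folklore for such spheres quotes "typically
25 nm/RIU" and a two-fold gain on halving the diameter; the exact
first-order result is lower for TE and the small-sphere gain is larger than
two-fold (higher-order size corrections grow as the sphere shrinks). TM,
which carries a radial field component and hence more evanescent intensity
in the medium, is the more sensitive polarization; both are reported.

## The synthetic-data generator

`simulation_scene()` encodes the study conditions: a 10 µm-radius
polystyrene sphere in water, dye envelope peaked at 590 nm (FWHM 60 nm),
gain window 615–625 nm (polystyrene absorbs more at shorter wavelengths, so
only the red modes lase), Q = 3×10³/1.5×10⁴ below/above threshold,
threshold 28 µW, a 2048-pixel detector. The comb is geometric --
λ_k = 2πRn_s/k with a TM comb offset 0.35 FSR and distinct amplitudes --
which makes the radius inversion exact by construction and is the point:
the generator and the analysis share the forward model that the analysis
claims to invert, and the tests close that loop. Mode amplitudes are
phenomenological (envelope-weighted), not electromagnetic.

Binding kinetics are single-exponential saturations with per-concentration
presets (saturation in ~1 min at 1600 nM through non-saturating at ≤20 nM,
plateau densities from 1.77×10⁻³ g/m² down to 1.2×10⁻⁴ g/m²); they encode
qualitative trends of static, diffusion-limited binding, not measured rate
constants. Wavelength noise defaults to 4 pm per point -- the detection
system's resolution, used as a noise floor assumption since no measured
noise figure is available. Optional photobleaching decay exists in real
data but is not modelled beyond an amplitude argument; spectra here are
stationary between time points.

What passing tests therefore do show: the inverse chain is the exact
inverse of the stated forward model, estimators are unbiased at realistic
noise, and decision rules hold their nominal error rates. What they do not
show: robustness to envelope drift, mode-order misidentification in dense
multi-order spectra, or non-exponential transport-limited kinetics.

## Numerical choices and edge cases

- Peak windows walk out to 5 % of the prominence above the local base,
  extend 50 % for baseline leverage, and are capped at neighbour midpoints;
  the walk tests only the floor level so single-sample noise cannot
  truncate a window.
- Fits with FWHM under two sample spacings warn (under-resolved); fewer
  than five samples in a window is an error, not a guess.
- `detect_peaks` on a constant spectrum returns an empty table; downstream
  functions treat empty inputs as errors with messages naming the
  precondition.
- Mode tracking re-centres its window on the previous fit and refuses
  steps larger than FSR/2 when the FSR is known (mode hopping is an
  ambiguity, not a measurement).
- The mode number is kept continuous exactly as the spacing formula yields
  it; rounding is opt-in.
- Degenerate threshold sweeps (equal slopes) are flagged, never
  extrapolated; intersections outside the data range warn.
- All stochastic generators take an explicit seed and restore the global
  RNG state; given (scene, seed) every output is bit-reproducible.
- Bessel evaluation: half-integer-order base routines are accurate through
  l ≈ 170 at these size parameters (verified against the independent
  recurrence implementation to ~10⁻¹² relative); the recurrence backend is
  also selectable as the production evaluator.

Problem sizes used by the validation suite -- 200 seeds for threshold
recovery, 100 seeds per concentration preset for plateau recovery, 1000
blank seeds for the false-positive rate, 50 seeds for FSR jitter -- were
chosen so each Monte-Carlo median is stable to well under the tolerance it
is compared against.

## Known limitations

- The 4 nM preset plateau (6.7 pm asymptotic shift against 4 pm/point
  noise, non-saturating record) is at the information limit: no estimator
  recovers its plateau to 10 % from a single 30-minute series, and the
  validation reports it as such rather than relaxing the condition.
- The adlayer model is the effective-radius first-order picture; no
  perturbation-theory correction, no coated-sphere Mie model, no
  multilayer optics.
- Amplitude physics (mode competition, gain saturation, photobleaching) is
  out of scope; only resonance positions and widths carry meaning in the
  simulator.
- Radiative Q is not computed: measured Q here is material- and
  instrument-limited, orders of magnitude below the radiative limit.

## A worked example

```{r example, eval = FALSE}
scene <- simulation_scene(noise = list(additive_sd = 0),
                          instrument = instrument_model(4096, c(610, 630)))
s <- simulate_spectrum(scene, pump_uW = 10)
peaks <- fit_peaks(s)
estimate_radius(peaks, n_s = 1.59)

sweep <- simulate_power_sweep(scene, seq(5, 100, length.out = 20),
                              slope_below = 2, slope_above = 40,
                              rel_noise_sd = 0.05, seed = 1)
fit_two_regime(sweep$power_uW, sweep$intensity)

ser <- simulate_binding_series(400, kinetics_preset(400), seed = 1)
saturation_metrics(ser)
lod_decision(ser, blank_noise_sd_nm = 0.004)

bulk_sensitivity(10, 1.59, 1.33, 620, "TE")
```
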