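# wgmsense

Quantitative analysis of fluorescence-based whispering-gallery-mode (WGM)
microsphere biosensors, for labs running dye-doped microsphere resonators
(typically ~20 µm polystyrene spheres on a fiber tip) as label-free
dip sensors: from raw emission spectra to resonance peaks, resonator
geometry, deposited-layer thickness, adsorbed protein surface density,
lasing threshold, binding kinetics and limit-of-detection decisions — plus
a seeded forward simulator so the entire pipeline can be validated without
instrument data.

## The models at the core

**Resonance tracking.** The emission spectrum is a dye envelope times a
comb of narrow modes. Peaks are fitted with Gaussians plus a local
baseline; Q = λ/Δλ. Two successive same-polarization modes give the mode
number and radius:

    m = λ_{m+1} / (λ_m − λ_{m+1}) + 1,      R = λ_{m+1} · m / (2π n_s)

**Shift inversion.** Adsorption shifts every mode: Δλ/λ = ΔR/R =
n_L·e/(n_s·R) gives the layer thickness e; the chain through the
Clausius–Mossotti polarizability

    α = (ε_r − 1)/(ε_r + 2) · 3Mε₀/(N_A ρ_m),
    σ_p⁻¹ = (n_s/n_L) · α / (ε₀ (n_s² − n_m²) δR),
    d = M / (N_A σ_p⁻¹)

converts a shift into the adsorbed surface mass density d (g/m², with
ng/cm² and pg/mm² pretty-printers).

**Lasing threshold.** Peak intensity vs pump power is piecewise linear;
`fit_two_regime()` finds the minimal-SSE split and intersects the two
lines.

**Electromagnetics.** `resonance_positions()` solves the homogeneous-sphere
Mie characteristic equation (Riccati–Bessel functions, Airy-zero asymptotic
bracketing, Brent refinement; every root cross-checked by an independent
Bessel implementation) and `bulk_sensitivity()` differentiates the
resonance wavelength against the medium index at fixed mode identity.

## Worked example

```r
library(wgmsense)

# a noiseless spectrum of the default 10 um polystyrene sphere in water
scene <- simulation_scene(noise = list(additive_sd = 0),
                          instrument = instrument_model(4096, c(610, 630)))
s <- simulate_spectrum(scene, pump_uW = 10)
peaks <- fit_peaks(s)
head(peaks[, c("center_nm", "fwhm_nm", "q_factor")], 2)
#>   center_nm   fwhm_nm q_factor
#> 1  611.5914 0.2038204 3000.639
#> 2  612.8995 0.2042774 3000.330
estimate_radius(peaks, n_s = 1.59)
#> <radius_estimate> R=10.0000 um from 8 mode pairs

# lasing threshold from a noisy 20-point pump sweep (true kink at 28 uW)
sweep <- simulate_power_sweep(scene, seq(5, 100, length.out = 20),
                              slope_below = 2, slope_above = 40,
                              rel_noise_sd = 0.05, seed = 1)
fit_two_regime(sweep$power_uW, sweep$intensity)
#> <threshold_fit> threshold=28.539 uW, slopes 2.106 -> 41.1, SSE=7.948e+04

# binding kinetics at 400 nM: saturation metrics and detection decision
ser <- simulate_binding_series(400, kinetics_preset(400), seed = 1)
saturation_metrics(ser)
#> <kinetics_summary> plateau=0.0009024 g/m2, t95=180 s, saturated=TRUE
lod_decision(ser, blank_noise_sd_nm = 0.004)
#> <lod_decision> DETECTED (tail mean 0.05031 nm vs threshold 0.004536 nm, z=33.28)

# electromagnetic bulk sensitivity near 620 nm, both polarizations
bulk_sensitivity(10, 1.59, 1.33, 620, "TE")$sensitivity_nm_per_riu
#> [1] 16.25759
bulk_sensitivity(10, 1.59, 1.33, 620, "TM")$sensitivity_nm_per_riu
#> [1] 21.31631
```

The fitted Q of ~3.0×10³ is the below-threshold linewidth regime; above
threshold the modes inside the gain window narrow to Q ≥ 1.5×10⁴. A
0.0987 nm saturation shift at 620.5 nm on the 10 µm sphere corresponds to
d ≈ 1.77×10⁻³ g/m² ≈ 177 ng/cm², about half of a full neutravidin
monolayer.

A thin command-line shell over these functions ships in
`inst/cli/wgmsense.R`:

```sh
Rscript inst/cli/wgmsense.R sensitivity --radius-um 10 --ns 1.59 --nm 1.33 \
        --near-nm 620 --pol TE
Rscript inst/cli/wgmsense.R fit-peaks inst/extdata/example_spectrum_synthetic.csv
```

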