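# guvfrap

Lateral lipid diffusion and membrane composition analysis for giant
unilamellar vesicles (GUVs), from fluorescence microscopy time series.

## What it does

**FRAP diffusion.** In a spot-bleach FRAP experiment the lower cap of a
GUV is imaged as a fluorescent disc, a circular spot of radius *w* is
bleached, and the spot's mean intensity is recorded as labelled lipids
diffuse back in. For 2-D free diffusion and a uniformly bleached disk
the fractional recovery is

    f(t) = exp(-2 τ_D / t) [ I₀(2 τ_D / t) + I₁(2 τ_D / t) ],   τ_D = w² / (4D)

and its half-crossing gives the conversion `D = 0.224 w² / t_half`.
The pipeline (`analyze_trace()`, `analyze_cohort()`) computes the
fractional recovery

    f_K(t) = (F_K(t) − F_K(0)) / (F_K(∞) − F_K(0))

from three reference intensities (first post-bleach frame, mean of the
last 8 recovery frames, mean of the 8 pre-bleach frames), fits
`y = y0 (1 − exp(−a t))` by least squares, extracts
`t_half = ln 2 / a`, converts to *D*, and applies the standard
inclusion rules: spot small relative to the membrane disc
(`√(A/π)/w ≥ 5`), short bleach pulse (`t_B ≤ t_half / 10`), mobile
fraction `M ≥ 0.75`, and no vesicle movement.

**Membrane composition.** For binary lipid mixtures imaged at the
vesicle equator, ring mean intensities (`measure_ring_intensity()`)
are regressed on the relative labelled-lipid concentration with the
intercept fixed at zero (`fit_zero_intercept()`) and normalized by the
fitted slope (`normalize_intensities()`), so 3:1, 2:2 and 1:3
(non-fluorescent : fluorescent) mixtures have expected values 1, 2
and 3.

**Synthetic data.** `generate_trace()`, `generate_cohort()`,
`render_frap_stack()` and `generate_composition_dataset()` simulate
traces, confocal-like stacks and composition datasets with known
ground truth, and `simulate_lattice_frap()` is a Brownian particle
simulator that reproduces the closed-form recovery independently of
it. Every analysis stage is therefore testable without microscope
data.

## Worked example

Simulate a 17-vesicle cohort at a ground-truth diffusion coefficient
of 1.0 µm²/s (5% ROI noise), run the full pipeline, and summarize:

```r
library(guvfrap)
traces <- generate_cohort("electro_DOPC", n_per_condition = 17, seed = 1,
                          curve_model = "exponential_model", sigma_noise = 5)
results <- analyze_cohort(traces)
head(results, 3)
#>         vesicle_id    condition   D_um2_s  t_half_s   a_per_s        y0
#> 1 electro_DOPC_001 electro_DOPC 0.9651700 0.9283339 0.7466572 0.9962275
#> 2 electro_DOPC_002 electro_DOPC 0.9747000 0.9192572 0.7540296 0.9906137
#> 3 electro_DOPC_003 electro_DOPC 0.9954111 0.9001306 0.7700518 1.0058447
#>           M qc_pass  qc_reasons
#> 1 0.9514386   FALSE pulse_ratio
#> 2 0.9539879   FALSE pulse_ratio
#> 3 0.9821227   FALSE pulse_ratio

group_summary(results$D_um2_s, "electro_DOPC")
#>          label  n     mean        sd        sem    median        q1       q3
#> 1 electro_DOPC 17 1.015284 0.1056108 0.02561438 0.9954111 0.9649672 1.074463
#>   whisker_low whisker_high
#> 1   0.8063105     1.213857
```

The cohort mean (1.02 ± 0.11 µm²/s) recovers the generator truth. The
per-vesicle `t_half ≈ 0.9 s` also shows why the pulse-duration QC rule
is strict here: a 0.1 s pulse is just over one tenth of the half-life,
so these vesicles are flagged by that rule while their fitted numbers
remain available — see the methods vignette
(`vignettes/guv-frap-methods.Rmd`) for discussion.

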