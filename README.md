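# dcehybrid

Pharmacokinetic analysis of T1-weighted dynamic contrast-enhanced
(DCE) MRI aimed at **very low blood–brain-barrier permeability**, the
regime of normal-appearing white matter, where the transfer constant
K^trans is of order 10⁻³ min⁻¹ and tissue enhancement is a few percent
of the baseline signal. For neuroimaging researchers quantifying
subtle barrier leakage — in small-vessel disease, dementia, multiple
sclerosis, radiotherapy follow-up — from ROI-averaged uptake curves or
parametric maps.

## The method

The unidirectional two-compartment model

    C_t(t) = v_p C_p(t) + K^trans ∫₀ᵗ C_p(τ) dτ

linearises into the **Patlak plot**: the apparent volume of
distribution v_d = C_t/C_p against concentration-stretched time
t_stretch = ∫C_p/C_p, with slope K^trans and intercept v_p. In
low-permeability tissue the plot is biased — backflux of tracer bends
the late points down (K^trans low, v_p high) and the division by C_p
distorts the noise.

The package's core is a three-step **hybrid estimator** that splits
the two parameters across the techniques that measure each best:

1. conventional Patlak fit (default t_stretch interval 85–250 s) for
   a provisional K^trans;
2. leakage-corrected **first-pass integral** for v_p: subtract
   K^trans ∫C_p from the tissue curve and take the ratio of the
   remaining intravascular area to the plasma area over the first
   pass of the bolus — a ratio insensitive to error in the supplied
   K^trans;
3. Patlak refit with the intercept pinned at the Step-2 v_p, leaving
   K^trans as the only free parameter.

Around it: SPGR signal physics (variable-flip-angle R1/M0 fitting,
post-injection R1 by signal subtraction, concentration via relaxivity
4.39 mM⁻¹s⁻¹), ΔR1 mapping with a four-colour white-matter
classification, interval-stability analysis, and a Rician-noise
Monte-Carlo framework with a synthetic arterial input function that
emulates a low-dose, 1.03-s-resolution protocol.

## Worked example

Simulate a white-matter uptake curve with backflux (modified Tofts
model, truths K^trans = 0.0074 min⁻¹, v_p = 0.024, v_e = 0.20) and fit
it both ways:

```r
library(dcehybrid)

cp <- synth_aif()                                   # synthetic plasma curve
ct <- tissue_conc_tofts(cp, kinetic_params(0.0074, 0.024, ve = 0.20))

fit_roi(ct, cp, "patlak")
#> <patlak_fit> Ktrans = 0.006781 /min, vp = 0.02496 (n = 112, interval 85-250 s, R2 = 0.9994)

hybrid_fit(ct, cp)
#> <hybrid_fit> Ktrans = 0.007033 /min, vp = 0.02413
#>   step 1 (Patlak 85-250 s): Ktrans = 0.006781 /min, vp = 0.02496
#>   first-pass window: 35.0-60.8 s
```

With zero noise, the deviations are pure backflux bias: the Patlak
plot is 4.0% high on v_p and 8.4% low on K^trans, while the hybrid
final estimates are within 0.5% (v_p) and 5.0% (K^trans) of truth —
the first-pass integral absorbs the leakage, and the pinned intercept
pulls the slope back up.

The Monte-Carlo study adds Rician noise and the SI-averaging scheme
(each repetition averages 100 noisy curves):

```r
cfg <- sim_config(noise_levels = 0.04, n_reps = 50, n_average = 100, seed = 1)
monte_carlo_pd(cfg)   # mean_pd / sd_pd shown here in percent
#>   method param  noise_level n_average mean_pd sd_pd  n fail_rate
#> 1 patlak ktrans        0.04       100   -7.80 12.40 50         0
#> 2 patlak vp            0.04       100    4.05 11.70 50         0
#> 3 hybrid ktrans        0.04       100   -4.59  6.40 50         0
#> 4 hybrid vp            0.04       100    0.76  2.00 50         0
```

Both the bias and the spread of the hybrid estimates are roughly half
those of the conventional Patlak fit. `ktrans_sweep()` maps where each
estimator degrades as true backflux grows, `stability_sweep()`
quantifies robustness to the fitting-interval choice, and
`plot_pd_summary()` / `autoplot()` draw the standard figures. Fitted
objects support `tidy()` and `glance()`.

A thin command-line front end for shell use is installed at
`system.file("cli", "dcehybrid", package = "dcehybrid")` with
subcommands `fit-roi`, `simulate-mc`, `sweep-ktrans` and `stability`.

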