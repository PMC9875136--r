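# kexqsm

Quantitative MRI stratification of multiple sclerosis (MS) lesions by
inflammatory status, for imaging scientists who want a tested, desk-scale
implementation of the whole chain: chemical exchange saturation transfer
(CEST) Z-spectra to per-voxel proton exchange rate (k<sub>ex</sub>) maps,
multi-echo phase to quantitative susceptibility maps (QSM), and per-lesion
classification into joint k<sub>ex</sub>/QSM positivity patterns.

## The science in brief

Gadolinium enhancement marks acute blood–brain-barrier disruption, but most
MS lesions are Gd-negative, and "Gd-negative" is not "inactive": iron
redistribution (visible as a susceptibility elevation, Δχ in ppb, on QSM)
and reactive-oxygen-species production (which raises the labile-proton
exchange rate k<sub>ex</sub> in s⁻¹) can persist. Stratifying Gd-negative
lesions by joint positivity —

| pattern | k<sub>ex</sub> | QSM |
|---|---|---|
| I | + | + |
| IIa | + | − |
| IIb | − | + |
| III | − | − |

— separates radiologically active from inactive lesions, and the fraction of
Pattern I lesions declines with disease duration.

The k<sub>ex</sub> quantification is the omega plot on direct-saturation
removed residuals. Each Z-spectrum (normalized water signal as a function of
saturation offset) is flipped and decomposed into two Lorentzians — the bulk
water line (whose centre is the voxel's B0 shift) and a composite peak near
+1.5 ppm for the remaining saturation-transfer mechanisms. The fitted water
line is subtracted and the residual read at the B0-corrected +3.5 ppm amide
offset. Under the labeling-efficiency model

```
R = (f k / R1w) * w1^2 / (w1^2 + k^2),      w1 = gamma * B1,
```

the inverse residual is linear in 1/w1², so a straight line through the
residuals measured at B1 = 2, 3, 4 μT yields

```
k_ex = sqrt(slope / intercept),
```

with the proton fraction f and the water relaxation rate R1w cancelling in
the ratio. QSM is reconstructed by thresholded k-space division (TKD) of the
dipole-convolution model, with the deterministic point-spread attenuation of
the thresholded kernel undone.

Because no patient data are distributable, all inputs are synthetic and
first-class: a Bloch–McConnell simulator generates multi-pool Z-spectra, a
digital phantom injects lesions with known Δk<sub>ex</sub>/Δχ and
nodular/ring profiles, a cohort generator emulates the duration-dependent
decline of inflammation, and a packaged 322-lesion fixture table carries the
published cohort's exact classification counts.

## Worked example

Classify the packaged lesion-count fixture:

```r
library(kexqsm)
fixture_report()
#> # A tibble: 5 × 3
#>   pattern     n pct_of_gdneg
#>   <fct>   <int>        <dbl>
#> 1 GdPlus    153         NA
#> 2 I         114         67.5
#> 3 IIa        16          9.5
#> 4 IIb        31         18.3
#> 5 III         8          4.7
```

153 of the 322 lesions enhance; of the 169 that do not, 67.5% are doubly
positive (Pattern I), 27.8% are positive on exactly one map, and 4.7% are
negative on both.

The omega-plot estimator on ideal residuals is exact:

```r
r <- ideal_residual(f = 0.0009, k = 700, r1w = 1, b1 = c(2, 3, 4))
round(r, 4)
#> [1] 0.2323 0.3578 0.4412
glance(omega_fit(r, c(2, 3, 4)))
#> # A tibble: 1 × 3
#>     kex    r2 valid
#>   <dbl> <dbl> <lgl>
#> 1   700     1 TRUE
```

And the full synthetic pipeline — Bloch–McConnell phantom, Lorentzian water
removal, omega plot, dipole inversion, ROI measurement, classification —
runs in well under a minute:

```r
cfg <- run_config(list(seed = 11,
  phantom = list(grid = c(24, 24), n_lesions = 2, lesion_radius = 3,
                 noise_sd = 0.002, delta_kex = 400, delta_chi = 30)))
res <- run_pipeline(cfg, "demo_run")
res$records |>
  dplyr::select(lesion_id, delta_kex, delta_chi, kex_positive,
                qsm_positive, qsm_shape, pattern)
#> # A tibble: 2 × 7
#>   lesion_id delta_kex delta_chi kex_positive qsm_positive qsm_shape pattern
#>       <int>     <dbl>     <dbl> <lgl>        <lgl>        <chr>     <fct>
#> 1         1      246.      15.9 TRUE         TRUE         ring      I
#> 2         2      445.      28.6 TRUE         TRUE         nodular   I
```

Both injected lesions (Δk<sub>ex</sub> = 400 s⁻¹, Δχ = 30 ppb above
normal-appearing white matter) come back doubly positive; the ring-profile
lesion is recognized as a ring on QSM and its disc-averaged elevations are
diluted relative to the uniformly filled nodular lesion, as they should be.
`run_pipeline()` writes the maps (NIfTI), lesion and patient tables (CSV), a
statistics report (JSON), the resolved configuration, and a hashed manifest
into the output directory. `autoplot()` methods display every map and
dataset type; `tidy()`/`glance()` return tibbles.

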