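---
title: "Quantifying and stratifying MS lesions with k_ex and QSM: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and stratifying MS lesions with k_ex and QSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kexqsm)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter, what
the synthetic data do and do not emulate, and the numerical decisions taken
where the method description leaves the implementation genuinely open.

## 1. The measurement chain

A chemical exchange saturation transfer (CEST) experiment saturates labile
protons at an offset from the water resonance and reads the water signal
after exchange has transferred saturation into the water pool. The
Z-spectrum is the normalized water signal as a function of saturation offset
(ppm). The package implements the full chain from Z-spectra to a lesion
stratification:

1. **Simulation** (`bm_zspectrum()`, `generate_phantom()`): multi-pool
   Bloch–McConnell propagation under continuous-wave saturation, one matrix
   exponential per offset.
2. **Decomposition** (`fit_two_lorentzian()`): the flipped spectrum `1 - Z`
   is modelled as a bulk-water Lorentzian (centre = per-voxel B0 shift) plus
   one composite Lorentzian near +1.5 ppm for the summed remaining transfer
   mechanisms (NOE, semisolid MT, other CEST pools).
3. **Direct-saturation removal** (`water_removed_residual()`): the fitted
   water line is subtracted and the residual read at the B0-corrected
   +3.5 ppm amide offset.
4. **Omega plot** (`omega_fit()`, `kex_map()`): residuals from the three
   saturation powers (2, 3, 4 μT; 1.5 s saturation; 3 T) are inverted
   through the labeling-efficiency line `1/R = a + b / w1^2`, giving
   `k_ex = sqrt(b / a)` per voxel. The proton fraction and water T1 cancel.
5. **QSM** (`echo_fit()`, `tkd_invert()`, `reference_map()`): per-voxel
   phase-vs-echo-time slopes give the field map (ppm); thresholded k-space
   division inverts the dipole convolution; values are referenced to
   normal-appearing white matter (NAWM) and reported in ppb.
6. **Classification** (`roi_delta()`, `positivity()`, `shape_classify()`,
   `assign_pattern()`): per-lesion elevations Δk_ex and Δχ against an NAWM
   reference ROI, positivity by a sign rule, QSM ring/nodular shape by a
   rim/core contrast, and the Gd⁺ / I / IIa / IIb / III pattern assignment.
7. **Cohort statistics** (`spearman_test()`, `mann_whitney_test()`,
   `kruskal_test()` + `dunn_posthoc()`, `fleiss_kappa()`, `icc21()`).

## 2. The Bloch–McConnell simulator

Each pool contributes three magnetization components; exchange couples every
component of a labile pool to water with forward rate `k` and back-rate
`f k` (detailed balance). The coupled linear system plus the longitudinal
recovery term is integrated exactly by a matrix exponential over the
saturation time, via eigendecomposition with a scaling-and-squaring
fallback. Assumptions: continuous-wave saturation (no pulse-train
structure), instantaneous readout of water Mz, and normalization by the
reference offset image (+39.1 ppm) exactly as the processing does it.

**Default pool set** (`default_pools()`):

| pool | f | k (s⁻¹) | R1 (s⁻¹) | R2 (s⁻¹) | δ (ppm) |
|---|---|---|---|---|---|
| water | 1 | — | 1.0 | 14 | 0 |
| amide | 0.0009 | variable (NAWM default 500) | 1 | 30 | +3.5 |
| composite | 0.002 | 20 | 1 | 200 | +1.5 |

The amide exchange rate is the quantity of interest; lesions add
`delta_kex` to it. The composite pool is deliberately weak and broad: it
exists so that the second Lorentzian has a real counterpart and so that the
"tissue k_ex is a weighted average of mechanisms" caveat is represented,
without dominating the +3.5 ppm readout. Water relaxation uses
white-matter-typical values at 3 T (T1 = 1 s, T2 = 71 ms). This matters
more than it looks: with a much longer water T1 the 1.5 s saturation stays
far from steady state, the direct-saturation lineshape is then strongly
non-Lorentzian, and no two-component decomposition can remove it. With
white-matter relaxation the line is near-Lorentzian (in steady state it is
exactly Lorentzian, with FWHM `2 sqrt(R2^2 + w1^2 R2 / R1)`, 7–15 ppm at
2–4 μT) and the removal is well posed. The relaxation constants are
configurable per pool.

**Offsets.** The default sampling (`default_offsets()`) is the reference
points +39.1 and +15.6 ppm, shoulders at ±6, ±5, ±4.5 ppm, and a dense
−4…+4 ppm grid in 0.25 ppm steps (41 offsets in total).

## 3. Why the Lorentzian fit is staged

A simultaneous 6-parameter fit of both Lorentzians is degenerate whenever
the measured line deviates from an exact Lorentzian sum — which a saturated
water line always does slightly. The optimizer then fits the water peak
better by splitting it between the two components (water centre drifting to
−0.5 ppm with the "composite" absorbing the other half), which destroys the
decomposition that water subtraction relies on. The fit is therefore staged
without feedback:

1. the water **centre** from the symmetric core of the line (parabolic
   vertex through the peak, refined on a ±0.6 ppm window) — under
   multi-power processing the centre is estimated once on the sharpest
   (lowest-power) spectrum and shared, because the B0 shift is a property of
   the voxel, not of the saturation power;
2. the water **amplitude and width** from the negative wing only (the
   labile pools sit at positive offsets), weighted toward the mirrored
   readout offset so the subtraction is most accurate exactly where the
   residual is read;
3. the **composite** on the water-subtracted remainder (skipped and recorded
   as zero when the remainder has no appreciable peak — a vanishing
   amplitude makes the centre and width unidentifiable);
4. a **joint refinement** of all six parameters, accepted only when it
   reaches an essentially exact fit (RSS < 1e−12). On data that truly are a
   sum of two Lorentzians this recovers the global decomposition to machine
   precision; on saturated in-vivo-like lineshapes it is rejected and the
   staged solution stands.

Bounds (amplitudes, centres, widths) follow the table in
`?fit_two_lorentzian`; the water-width ceiling of 20 ppm accommodates the
direct-saturation linewidth at the default powers. Two numerical details
worth knowing: starting values with magnitude ~1e−15 are snapped to exact
zero (the Levenberg–Marquardt implementation scales parameters by their
starting magnitude, and a tiny nonzero start yields a numerically singular
Jacobian column), and all starts are clamped strictly inside the bounds.

## 4. The residual and its spillover rescaling

The residual is `[1 - Z] - L_water` evaluated at `+3.5 + δw` ppm, averaged
over a ±0.25 ppm symmetric window (exact when the residual spectrum is flat
or symmetric; it suppresses single-sample noise at the readout). Only the
water peak is subtracted — the composite tail at +3.5 ppm deliberately
remains, so the estimated rate is a weighted average of the mechanisms
present.

By default the subtraction residual is rescaled by the measured Z and the
fitted water line at the target (`spillover_correction = TRUE`). The
exchange-transfer dip rides on the water magnetization that survives direct
saturation, and that baseline shrinks as the power grows; in the
steady-state weak-pool limit the raw subtraction equals
`(R_ex / R1w) * Z * Z_water`. Without undoing that factor the residual is
not monotone in B1 at these powers and the omega-plot slope can turn
negative everywhere. With it, the residual is proportional to the labeling
efficiency and the inversion behaves. `spillover_correction = FALSE` gives
the plain subtraction.

**Accuracy envelope.** On ideal residuals the estimator is exact (tested to
1e−6 relative). On Bloch–McConnell data at the study's acquisition settings
the chain is strictly monotone in the true rate but biased — the acceptance
script reports the homogeneous-phantom mean; at a true 500 s⁻¹ it sits
roughly 30% high, with spatial CV far below 1% — because neither the finite
saturation time nor the second-order pool coupling is part of the inverted
model. Bias of this kind cancels in Δk_ex-style contrasts to first order
and does not affect positivity calls against the same-biased NAWM
reference, which is how the map is used downstream.

## 5. QSM choices

The forward model is the standard k-space dipole kernel
`D = 1/3 - (k·b)^2 / |k|^2`, `D(0) = 0`. The inverse is thresholded k-space
division at threshold 0.2 (configurable in (0, 1/3]), with the
deterministic point-spread attenuation of the thresholded kernel undone by
dividing by `mean(D / D~)` (`psf_correct = FALSE` gives the plain variant;
plain TKD under-recovers sphere interiors by roughly the thresholded cone
fraction). Morphology-regularized inversion is out of scope: the package's
surface is synthetic round-trip recovery, not in-vivo streak suppression.
There is no background-field removal stage — the phantoms contain no
background sources — but `reference_map()` is an explicit, separate step so
a real-data pipeline can insert one before it.

**Single-slice geometry.** For 2D maps the package models a
through-plane-invariant (cylindrical) geometry with the static field lying
in the slice plane. The through-plane spatial frequency is then identically
zero and the 3D kernel reduces exactly to a 2D kernel, so the 2D forward
and inverse operators are mutually consistent while still exercising the
zero-cone regularization. (A replicated thin-slab embedding with
through-plane B0 is not self-consistent: the slab field varies
through-plane, and inverting a replicated central-slice field badly
underestimates lesion amplitudes.) 3D volumes use the ordinary 3D kernel
with B0 along the third axis.

Echo fitting assumes unwrapped phase; the synthetic echo train (8 echoes,
first TE 4.3 ms, spacing 4.8 ms) keeps |φ| well below π at tissue-scale
fields, and any voxel whose phase jumps by more than π between adjacent
echoes is flagged unreliable rather than unwrapped.

## 6. Classification rules

* **Elevation**: mean over the lesion ROI minus mean over its NAWM ROI,
  sentinel (`NaN`) voxels excluded; fewer than 5 valid voxels in either ROI
  flags the lesion unevaluable.
* **Positivity**: strict sign rule by default (`delta > 0`), the numeric
  surrogate for the radiologists' visual call; `tau` (absolute floor) and
  `z_min` (multiples of the NAWM SD) are hooks for a contrast threshold,
  since a visual reading plausibly implies one. The fixture-based results do
  not depend on this choice.
* **Shape**: the lesion mask is split into a rim (outer 30% of the
  effective radius, by iterated 4-neighbour binary erosion) and a core; ring
  means the NAWM-referenced rim mean is at least 1.2× the core mean with
  both positive. A tie at exactly the ratio counts as ring; masks too small
  to erode are nodular by convention and flagged. Shape applies to QSM (and
  Gd) only — exchange-rate maps are never shape-classified.
* **Eligibility**: lesions below 3 mm long axis (at the configured in-plane
  resolution, default 1.875 mm/voxel) are retained in the table but carry
  no pattern.
* **NAWM placement** (`build_rois()`): the reference box is mirrored across
  the vertical midline; if the mirrored box touches any lesion, an adjacent
  clear box is searched on a ring around the lesion.
* **Patterns**: all Gd-enhancing lesions form one category; Gd-negative
  lesions map to I/IIa/IIb/III by the joint flags. The assignment is total
  on the 8-point flag cube, and Pattern II is reported both merged and
  split.

## 7. The synthetic cohort and the fixture

`generate_cohort()` emulates the cohort-level structure: lognormal disease
durations (mean 3.86 y, SD 4.77 y), about 322/30 lesions per patient,
enhancing fraction 153/322 with ring fraction 61/153, and per-lesion
positivity probabilities that decline on the logit scale with duration
(anchored to 130/169 and 145/169 at the mean duration). One latent Gaussian
copula per lesion drives both the positivity flags and the magnitude
quantiles, so Δk_ex and Δχ are positively rank-correlated across lesions
and the fraction of doubly positive lesions falls with duration — the two
correlation signs the cohort analysis reproduces. Magnitudes come from
sign-truncated normals with the reported group means and SDs (e.g.,
155 ± 103.7 s⁻¹ and 28.19 ± 12.87 ppb for doubly positive lesions,
225.0 ± 119.2 vs 95.7 ± 104.8 s⁻¹ for ring vs nodular enhancement).

What the generator does **not** emulate: anatomy (lesions are discs on a
homogeneous background), registration errors between modalities, Rician
noise (Gaussian on the normalized signal is used; at the simulated SNR the
difference is negligible), partial-volume effects, vein/artifact exclusion
inside QSM ROIs, and radiologist variability. Passing tests therefore show
that the algorithms are correct and stable under the stated models — not
that they would reproduce in-vivo effect sizes.

`lesion_fixture()` is the one place real numbers enter: a 322-row label
table whose marginal and joint counts equal every published classification
count. Cells the report does not print are filled deterministically
(maximal k_ex⁺/QSM⁺ overlap within the enhancing group, whose
exchange-positive count 131 is forced by the totals; QSM ring shares at the
Gd ring fraction), and construction self-checks every printed sum. One
printed percentage (85.7% for 145/169) disagrees with its own fraction
(85.8%) by a rounding slip; the package reproduces the count exactly.

## 8. Statistics

Nonparametric throughout, matching the cohort analysis: Spearman rank
correlation (mid-ranks; exact permutation p by full enumeration for n ≤ 10,
chunked by the leading rank to bound memory, t approximation above),
Mann–Whitney U (exact split enumeration when `n_a n_b <= 64`, tie-corrected
normal approximation with continuity correction otherwise), tie-corrected
Kruskal–Wallis (delegating to `stats::kruskal.test()`, with the all-tied
degenerate case reported as H = 0, p = 1) with Dunn z pairwise follow-ups
under the Dunn–Šidák adjustment `1 - (1 - p)^m`, Fleiss' kappa for the
three-reader categorical calls, and ICC(2,1) — two-way random effects,
absolute agreement, single measure, the conventional interobserver choice
for continuous measurements; the form is fixed and documented rather than
configurable. A parametric branch (Welch t) exists behind
`compare_groups(parametric = TRUE)` but nothing in the default pipeline
uses it. All tests are two-sided.

## 9. Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale sizes chosen so
the whole suite runs on one CPU in minutes: 12–32 voxel square phantoms
(with per-spectrum memoization, identical voxels are processed once), 64³
sphere round trips, 100-replicate cohort ensembles, and 10,000-replicate
null calibrations. Every stochastic step draws from an explicit seed;
generators are byte-reproducible under a fixed seed, and derived seeds stay
below 2³¹.

## 10. Known limitations

* The omega-plot inversion assumes the ideal labeling-efficiency model;
  its systematic bias on realistic spectra is documented above rather than
  corrected, and absolute k_ex values should be read with that in mind.
* Continuous-wave saturation only; pulse-train saturation schemes are not
  modelled.
* TKD is a deliberately simple inversion; no morphology prior, no
  background-field removal, no phase unwrapping.
* Registration is translation-only, matching the single-slice synthetic
  regime; deformable motion is out of scope.
* The cohort generator reproduces signs and rough magnitudes of the
  published group structure, not patient-level effect sizes, which would
  require the unavailable clinical data.
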