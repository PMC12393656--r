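---
title: "Simulated K-edge imaging with a four-threshold photon-counting CT: models, parameters, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated K-edge imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`kedgesim` reproduces, entirely in software, the measurement chain of a
dual-contrast phantom experiment on a clinical photon-counting CT (PCCT):
energy-binned acquisition, calibration, image-domain multi-material
decomposition into water/iodine/gadolinium maps, and the quantitative
statistics usually reported for such experiments. This vignette documents
the models, every tunable that matters, the numerical choices, and what the
simulation can and cannot say about a real scanner.

## Physical model

**Attenuation.** Mass-attenuation tables for water, iodine and gadolinium
(10–150 keV, 1 keV step, cm²/g) are packaged under `inst/extdata/`,
generated by log–log interpolation of a sparse anchor grid transcribed from
standard physical reference compilations (`data-raw/` holds the generator).
The K-edge of iodine (33.2 keV) and gadolinium (50.2 keV) is represented by
a *duplicated grid point* holding the below-edge and above-edge values;
`mass_attenuation_at()` never interpolates across it. Transcription accuracy
is a few percent — sufficient, because the study's observables are
structural (linearity, noise scaling, separability), not absolute
attenuation values.

**Spectrum.** The tube is modeled as a Kramers-law bremsstrahlung shape,
`w(E) ∝ (E_max/E − 1)`, attenuated by a fixed water-equivalent inherent
filtration (default 2.5 g/cm², giving a mean energy of ≈54 keV at 140 kVp),
clipped below the lowest detector threshold (20 keV) and above the tube
voltage, and normalized to unit fluence. Characteristic tungsten lines are
omitted: any smooth polychromatic spectrum spanning both K-edges preserves
the effects under study. The filtration value is a config knob
(`tube_spectrum(filtration_g_cm2 = ...)`); hardening it was evaluated and
does not qualitatively change any result.

**Detector.** An ideal counting detector: every photon lands in exactly one
of the four bins `[20,55)`, `[55,72)`, `[72,90)`, `[90,140]` keV with no
pulse pileup, charge sharing or spectral distortion. Expected counts follow
the polychromatic Beer–Lambert model,
`N_b = n0 · Σ_{E∈b} w(E) · exp(−Σ_m (μ/ρ)_m(E) L_m)`.

**Dose.** CTDIvol maps linearly to incident photons per detector channel:
`n0 = 1.2·10⁴ photons/ray/mGy` by default. The constant is a documented
tunable, not a fit: absolute dose-to-fluence conversion is scanner-specific
and unpublished. With this default the simulated iodine-map background
noise across 1/2/4/8 mGy comes out at ≈1.5/1.1/0.8/0.5 mg/mL — the order of
magnitude clinical systems report.

**Geometry.** 2D parallel-beam, 360 angles over 180°, detector spacing
equal to the 0.59 mm pixel spacing, 256×256 reconstruction. A dual-source
helical fan-beam geometry contributes nothing to the studied image-domain
ROI statistics, so it is deliberately not modeled. Noise is injected in the
*count (sinogram) domain* and propagated through filtered backprojection
(Ram-Lak × Hann), so bin-image noise is spatially correlated as on a real
scanner — CNR and decomposition noise amplification depend on this.
Log-normalization clamps counts at 0.5 so fully absorbed rays stay finite.

## Phantoms

The study phantom is a 10 cm water cylinder with 6 mm-radius syringe-like
inserts on a 30 mm ring: 8 pure inserts (I and Gd at 1/2.5/5/10 mg/mL) or 6
mixed inserts (I:Gd = 1:2.5, 2.5:1, 2.5:2.5, 2.5:5, 5:2.5, 5:5 mg/mL).
The calibration phantom holds a single centered vial (water, I 13.5 mg/mL,
or Gd 10.0 mg/mL) in a body of 10/20/30/40 cm diameter (extension rings).
The calibration vial radius equals the study insert radius (6 mm): per-unit
signatures are secants of a mildly nonlinear response, and matching the
contrast path length between calibration and measurement keeps that secant
representative. Rasterization uses 4×4 supersampling; a 3D thorax phantom
is replaced by this 2D slice because every reported quantity is a per-slice
ROI statistic, and the 15-slice averaging of a volumetric protocol is
emulated by pooling 15 independent noise realizations per scan (3 repeat
scans per condition, each with its own derived seed).

## Calibration model

For each (material, diameter, dose) cell the protocol reconstructs the four
bin images and measures the central-vial ROI (60% of the vial diameter) —
48 records under defaults. The fitted model has two parts:

1. **Water pre-correction.** Per bin and per diameter, a polynomial in the
   raw bin value (default order 2, through the origin) maps water to a
   diameter-independent reference — the thin-object effective water
   attenuation of the unattenuated spectrum. It is fitted to radial ring
   means of the water-phantom interior. Two safeguards keep the mapping
   monotone for contrast pixels far above the water band: when the observed
   water spread is below 1% (e.g. a monoenergetic beam) or when the
   quadratic would lose monotonicity over the fitted range, the fit falls
   back to a linear rescaling; beyond the fitted range the mapping always
   continues linearly (C¹). In practice the quadratic term rarely survives
   these guards — an image-domain *value* mapping cannot simultaneously
   flatten radial cupping (many raw values → one target) and stay monotone
   for insert pixels, so the correction is effectively a per-(bin, diameter)
   rescaling that normalizes the mean water level, leaving ≈1% residual
   cupping in the softest bin. This is a deliberate approximation of an
   unpublished vendor correction; a projection-domain linearization would
   flatten cupping better but would not match the published image-based
   processing order (images are corrected, then decomposed).
2. **Bin signatures.** Per diameter,
   `s_m = (corrected mean of material m − corrected mean of water at the
   same diameter and dose) / concentration`, averaged over doses (signatures
   are dose-independent in expectation) and interpolated linearly between
   diameters (they are diameter-dependent through beam hardening). The
   water column of the 4×3 signature matrix is the reference water vector
   itself. The iodine and gadolinium signatures are ≈25–30° apart — the
   K-edge separability that makes the three-material problem solvable; the
   fit errors out if the matrix loses rank.

## Decomposition

Per pixel, unconstrained, unweighted ordinary least squares
`x̂ = argmin ‖b − S x‖²` (4 equations, 3 unknowns), one QR factorization of
`S` reused for all pixels. No non-negativity: background noise in the
contrast maps is signed, and clipping would bias Bland–Altman statistics.
Identity weighting across bins follows the published processing
description; a variance-weighted variant would change noise propagation and
is intentionally not the default.

**Known accuracy floor.** With a single-concentration calibration and the
wide 20–55 keV first bin (which contains iodine's K-edge), intra-bin and
cross-material spectral hardening leave a *deterministic* decomposition
error of roughly +1 to +4% for iodine and −1 to −9% for gadolinium at 1–5
mg/mL, worst in mixtures where the companion agent hardens the local
spectrum. This is a property of the linear image-domain model itself, not
of noise: it persists in noiseless runs and mirrors the
concentration- and solution-type-dependent bias that real K-edge phantom
studies report. Users needing sub-percent accuracy would have to calibrate
per concentration or decompose in the projection domain — both outside this
package's scope.

## Evaluation

- ROIs: centered on each insert, radius 0.6× insert radius (≈117 pixels at
  the default grid; a floor of 50 pixels is enforced), plus one background
  ROI at the holder center; mean and sd are computed over the pooled
  realizations.
- CNR `(insert mean − background mean)/background sd`; its linear trends
  against concentration (at the top dose) and against dose (at 5 mg/mL) are
  ordinary least-squares fits reported with R².
- Bias: with no independent reference, 8 mGy serves as baseline;
  `bias(dose) = mean(dose) − mean(8 mGy)` per insert/repeat, aggregated as
  mean ± sd per (material, solution type, dose).
- Bland–Altman: mean difference and ±1.96·sd limits of agreement (sample
  sd, n−1); a percentile variant (2.5th/97.5th) is available as a config
  alternative, since published "95th percentile confidence interval" phrasing
  is conventionally read as the 1.96-sd limits.
- Test grid: Mann–Whitney for two-level factors (material, solution type),
  Kruskal–Wallis + Dunn post hoc for multi-level factors (dose,
  concentration), applied to both noise and dose-baseline bias. The
  familywise cutoff is `alpha / n`, where `n` is the number of p-values the
  grid itself produces — the published grid's 117 comparisons are not
  enumerable from its description, so the package sizes the correction from
  its own grid and exposes `n_comparisons` as a parameter. (For reference,
  0.05/117 = 0.0004 at one significant figure.) Dunn's z uses mean ranks
  with the standard tie term; Kruskal–Wallis and Mann–Whitney come from the
  stats package, the latter exact for small untied samples.

## Reproducibility and problem sizes

A single master seed deterministically derives one seed per
(mode, dose, repeat, realization) plus a calibration seed
(`study_seeds()`), so any condition can be re-simulated in isolation and a
manifest of seeds accompanies every output bundle. The default full study
(2 modes × 4 doses × 3 repeats × 15 realizations at 256², plus 48
calibration cells) runs in roughly 10–15 minutes on one CPU; the test suite
uses the same design with 5 realizations per scan and 240 projection
angles where full fidelity is not needed, and the acceptance script runs
the pure-phantom arm at 8 mGy with the full 3 × 15 design in a few
minutes. These sizes were chosen so that sampling error is far below every
tolerance asserted in the tests.

## What passing tests do and do not show

The synthetic study emulates: K-edge separability under a realistic
polychromatic spectrum, Poisson dose scaling (background noise exponent
−0.5), beam-hardening cupping and its water correction, slice-averaged ROI
statistics, and the full nonparametric reporting pipeline. It does **not**
emulate detector non-idealities, scattered radiation, helical/fan-beam
sampling, vendor reconstruction kernels or iterative denoising. Absolute
CNR, noise and bias values of a physical scanner therefore cannot be
validated here — what the tests establish is the *structure* of the
results: CNR linear in concentration (R² ≥ 0.99), noise dependent on dose
but not on concentration or solution type, mixed-solution performance not
exceeding pure-solution performance, and exact agreement of every
statistical primitive with closed-form or enumerated oracles.
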