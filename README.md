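# kedgesim

Simulation and analysis of **K-edge imaging on a four-threshold
photon-counting CT (PCCT)** system: from energy-resolved X-ray physics
through calibration-based multi-material decomposition to the quantitative
statistics a phantom study reports.

## The problem

Photon-counting detectors classify individual photons into energy bins.
With four thresholds (here the clinical configuration 20/55/72/90 keV at
140 kVp) an acquisition yields four bin images, enough to solve per pixel
for **three basis materials**: water, iodine (K-edge 33.2 keV) and
gadolinium (K-edge 50.2 keV). The abrupt attenuation jump at each K-edge
gives iodine and gadolinium distinguishable bin signatures — this is what
makes *dual-contrast* imaging (both agents quantified in a single scan)
possible at all.

`kedgesim` is a desk-scale, fully synthetic re-creation of such a phantom
study, aimed at researchers who want a transparent, reproducible sandbox
for the image-domain decomposition chain:

1. **Physics** — tabulated mass-attenuation curves with explicit K-edge
   discontinuities, an analytic bremsstrahlung tube spectrum, and a
   polychromatic Beer–Lambert forward model for expected bin counts.
2. **Phantoms** — a 10 cm water-equivalent holder with syringe inserts:
   pure solutions at 1/2.5/5/10 mg/mL and mixed I:Gd ratios
   (1:2.5, 2.5:1, 2.5:2.5, 2.5:5, 5:2.5, 5:5 mg/mL); calibration vials
   (water, I 13.5 mg/mL, Gd 10.0 mg/mL) in bodies of 10–40 cm diameter.
3. **Acquisition** — parallel-beam projection, Poisson count noise scaled
   by CTDIvol (1/2/4/8 mGy, 3 repeats), log-normalization and filtered
   backprojection per bin.
4. **Calibration + decomposition** — per-bin beam-hardening water
   correction and per-unit bin signatures fitted from the calibration
   scans; then per-pixel unconstrained least squares
   `x̂ = argmin_x ‖b − S x‖²` with the 4×3 signature matrix `S`.
5. **Evaluation** — ROI means/stds (ROI covering 60% of each sample's
   diameter, 15 pooled noise realizations emulating slice averaging),
   Bland–Altman agreement, CNR `(insert − background)/background sd` and
   its linear trends, a dose-baseline bias table, and a nonparametric test
   grid (Mann–Whitney, Kruskal–Wallis + Dunn, Bonferroni-corrected).

## Worked example

```r
library(kedgesim)
library(dplyr)

# a reduced run: pure phantom, highest dose, one repeat of 2 realizations
cfg <- study_config(modes = "pure", doses_mgy = 8, repeats = 1,
                    n_realizations = 2,
                    calibration_diameters_cm = c(10, 20),
                    calibration_doses_mgy = 8, master_seed = 7)
study <- run_full_study(cfg)

study$cnr |> filter(material_map == "iodine", true_concentration > 0) |>
  select(insert_id, true_concentration, cnr)
#> # A tibble: 4 × 3
#>   insert_id     true_concentration   cnr
#>   <chr>                      <dbl> <dbl>
#> 1 pure_I1_Gd0                  1    2.39
#> 2 pure_I2.5_Gd0                2.5  4.55
#> 3 pure_I5_Gd0                  5    7.86
#> 4 pure_I10_Gd0                10   14.8

glance(study)
#> # A tibble: 1 × 6
#>   r2_cnr_conc_iodine r2_cnr_conc_gadolinium noise_iodine_low_dose ...
#> 1              1.000                  0.998                 0.719 ...
```

CNR grows linearly with concentration (about 1.4 per mg/mL of iodine in
this reduced run), and the iodine-map background noise at 8 mGy sits near
0.7 mg/mL here (0.54 at the full 15-realization pooling).
`autoplot(study)`, `plot_cnr_dose(study)` and `plot_bland_altman(study)`
give the standard figures; `write_outputs(study, "out/")` writes the CSV
tables, float-TIFF material maps and a YAML manifest that records every
seed. A command-line front end is available too:

```sh
Rscript inst/cli/kedgesim full-run --config config.yaml --out out/
```

## Scope

The simulator is 2D parallel-beam with an ideal counting detector: no
pulse pileup, charge sharing, helical geometry or vendor iterative
reconstruction. Those effects set a real scanner's absolute bias/CNR/noise
numbers, which are therefore not reproduced exactly here — the structural
behavior (linearity of CNR, dose^(−1/2) noise, dose-only noise dependence,
pure-vs-mixed performance) is the target. See the methods vignette
(`vignettes/kedge-imaging-methods.Rmd`) for the model, its assumptions and
its limitations.
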