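# spheromech

Quantitative biomechanics of multicellular spheroids from two complementary
experiments:

- **Fusion kinetics.** When two spheroids are placed in contact they coalesce
  like highly viscous liquid drops driven by surface tension. The squared
  normalised neck radius follows

  ```
  (r0 / R0)^2 = 2^(2/3) * (1 - exp(-t / tau)),      tau = 2^(2/3) R0 eta / Gamma
  ```

  where `r0` is the neck radius, `R0` the initial average radius of the pair,
  and `tau` the coalescence time constant. The ratio `Gamma/eta` — the
  **visco-capillary velocity** (µm/h) — is the tissue-intrinsic fusion speed.
  The package measures `r0(t)` and the lobe radii from time-lapse doublet
  images (or takes pre-measured series), fits `tau` per pair, and aggregates
  per group with the velocity-versus-radius correlation test.

- **Nanoindentation.** Load–dwell–retract indentations with a spherical tip
  (radius R = 9 µm, peak depth 3.5 µm, 1 s dwell) are analysed two ways:
  the shallow loading segment (depth ≤ 0.1 R = 900 nm) with the Hertz model
  `F = (4/3) E/(1-nu^2) delta^(3/2) sqrt(R)` for the Young's modulus, and the
  complete cycle with **Ting's solution** for viscoelastic contact under
  **power-law rheology**, `E(t) = E1 t^(-alpha)`, inverting for the
  relaxation scale factor `E1` (modulus at 1 s) and exponent `alpha`
  (0 = solid-like, 1 = fluid-like).

- **Tissue-level quantities.** The surface tension scale `Gamma ~ E * R0`
  (order-of-magnitude estimate), the apparent viscosity
  `eta = Gamma / (Gamma/eta)` in Pa·h, stiffness/tension fold ratios, and
  group comparisons (Shapiro–Wilk and Pearson chi-square normality checks,
  one-way ANOVA, Bonferroni pairwise tests).

Because such recordings are rarely shared, the package includes first-class
synthetic generators — fusion trajectories, rendered doublet image stacks,
and indentation cycles — so the whole pipeline is testable end to end.
It is intended for tissue-engineering and biomechanics groups working with
spheroid fusion assays and piezo-driven nanoindenters.

## Worked example

```r
library(spheromech)

# a cohort of 12 fusing pairs with ground-truth Gamma/eta = 8.4 um/h
cohort <- generate_cohort(cohort_spec(
  n_pairs = 12, radius_mean = 100, radius_sd = 20,
  vcv_um_per_h = 8.4, group_label = "RPE-RPE", seed = 1
))
fits <- fit_cohort(cohort, window = c(0, 48))
aggregate_group(fits)
#>   group       n vcv_mean vcv_sd tau_mean tau_sd cor_vcv_R0 cor_p
#> 1 RPE-RPE    12     8.27  0.329     18.3   1.79      0.291 0.359

# one indentation cycle of a 1.63 kPa, alpha = 0.16 sample with force noise
curve <- simulate_indentation_curve(indent_sim_config(
  E1 = 1630, alpha = 0.16, force_noise_sd = 1e-9, seed = 2
))
fit_plr(curve)
#> PLR fit: E1 = 1633 Pa, alpha = 0.160

tissue_mechanics(E_Pa = 1630, R0_um = 100, vcv_um_per_h = 8.4, group = "RPE-RPE")
#>   group    E_Pa R0_um vcv_um_per_h gamma_N_per_m apparent_viscosity_Pa_h
#> 1 RPE-RPE  1630   100          8.4         0.163                  19405.
```

The group summary recovers the injected visco-capillary velocity
(8.27 ± 0.33 µm/h vs 8.4 µm/h ground truth) with no significant
velocity–radius correlation (p = 0.36), as the coalescence model predicts:
`tau` grows with `R0` so their ratio is radius-free. The viscoelastic
inversion recovers E1 within 0.2% and alpha within 0.001 under realistic
force noise. The apparent viscosity of ~1.9 × 10^4 Pa·h combines the
indentation-derived tension estimate (0.163 N/m) with the fusion-derived
velocity.

Each fitted object supports `tidy()`, `glance()` and `autoplot()`; the
full synthetic-to-report run is available as `run_pipeline()` driven by a
YAML/JSON config (see `?run_pipeline`).

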