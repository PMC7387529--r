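---
title: "Models and methods behind spheromech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spheromech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromech)
```

This vignette explains the models the package implements, the assumptions
they rest on, the numerical choices made where the design was genuinely
open, and what the synthetic generators do and do not emulate.

## The liquid-drop coalescence model

Two spheroids in contact are treated as highly viscous droplets coalescing
under an effective surface tension $\Gamma$ against a tissue viscosity
$\eta$. The squared normalised neck radius follows

$$\left(\frac{r_0}{R_0}\right)^2 = 2^{2/3}\left(1 - e^{-t/\tau}\right),
\qquad \tau = 2^{2/3} R_0 \frac{\eta}{\Gamma},$$

with $r_0$ the neck radius, $R_0$ the initial average radius of the pair
and $\tau$ the time constant. The plateau $2^{2/3}$ is not a free
parameter: it is the volume-conservation limit of two equal drops merging
into one sphere. `fit_liquid_drop()` therefore fits $\tau$ alone by
default; a `free_amplitude` mode exists as a diagnostic (on good data the
fitted amplitude lands on $2^{2/3} \approx 1.587$, which is one of the
package's acceptance checks). The ratio $\Gamma/\eta$, the
*visco-capillary velocity* (µm/h), is the model's radius-free speed scale:
$\tau \propto R_0$ under the model, so a cohort sharing one $\Gamma/\eta$
shows a $\tau$–$R_0$ proportionality but no velocity–radius correlation.
`aggregate_group()` reports exactly this Pearson test.

**Assumptions and limits.** The model assumes constant radii, full
liquid-like rearrangement and no elastoplastic resistance. Young,
compacting spheroids violate the first assumption: their radii shrink
during the assay, and only the early kinetics follow the model. The
package encodes this as the default fit window: the first 6 h for
spheroids aged ≤ 3 days (`select_early_window()`), the full recorded range
otherwise. Spheroids with extensive extracellular matrix violate the
second assumption; for them the fitted parameters are *effective*
quantities and the fit quality (adjusted $R^2$, computed on the
$(r_0/R_0)^2$ scale with $p$ the number of free parameters) is part of the
result, not a formality.

**Estimator.** The default objective minimises log-scale residuals of
$y = (r_0/R_0)^2$. Neck measurements are positive with errors that grow
with the neck, i.e. multiplicative noise; on that error structure raw
least squares is strongly heteroscedastic (the saturated late points carry
~10% absolute errors while the informative early points carry ~1%), which
roughly doubles the spread of $\hat\tau$ on a 9-point schedule. Log-scale
residuals are the variance-stabilising transform for multiplicative error
and are unbiased to first order; `weighting = "none"` restores raw least
squares for comparison. Points with $y = 0$ (pre-touch frames) carry no
information about $\tau$ under the model and are excluded. Missing frames
are dropped, never interpolated — a 9-point series cannot support
imputation. The initial guess for $\tau$ is the time at which $y$ first
exceeds half its final observed value; the optimiser restarts from three
spread values before flagging non-convergence, and a fit whose $\tau$
exceeds 50× the observed time range is flagged as unresolved (a flat
series cannot distinguish large $\tau$ from infinite).

$R_0$ is frozen at its first-frame value even for compacting spheroids,
because the model normalises by the *initial* average radius; the
generator's compaction acts on the simulated geometry, not on the
normalisation.

## Imaging: from doublet silhouettes to neck series

`segment_doublet()` is deliberately parameter-free: Otsu global
thresholding, hole filling, and retention of the largest connected
component (two components when a comparably sized second object exists —
a not-yet-touching pair). Stereomicroscope images show dark spheroids on a
light field; synthetic silhouettes are bright on dark, so polarity is an
argument.

`measure_pair_geometry()` finds the doublet axis as the principal axis of
the foreground and builds a width profile (foreground area per unit axial
length) along it. The neck plane is the *deepest interior valley*: the bin
whose smoothed width sits furthest below the enclosing maxima on both
sides. This criterion is robust to the ±1-px ripple that axis-oblique
binning produces, and it degrades gracefully: a fully fused, unimodal mask
has no valley deeper than the ripple and raises `"neck undefined"`. Such
frames are excluded from fitting rather than assigned the theoretical
plateau value — the plateau should be inferred from the data, not imposed.

Sub-pixel geometry comes from circle fits. Away from the neck each lobe's
outer boundary is an exact circular arc, so boundary pixels on either side
of the neck plane (clear of the overlap kink) are fitted with algebraic
circles. Boundary pixel centres sit about half a pixel inside the true
edge, so half a pixel is added to the fitted radii. The neck radius is
then the half-chord of the fitted circle pair — on ideal two-sphere
geometry identical to half the minimal width, but far less sensitive to
pixelation, which matters for thin necks where the raw profile minimum is
biased upward by the adjacent chords. A direct area-per-length or
split-mask-area estimate was rejected for the same reason: each half of an
overlapping doublet loses half the lens area, biasing area-equivalent
radii low by several percent at moderate overlap. For fully separated
components, area-equivalent radii *are* exact and are used.

These choices hold the round-trip error (render → segment → measure)
below one pixel at 2 µm/px across random geometries with
$r_0 / \min(R_a, R_b)$ up to 0.8, including arbitrary doublet
orientations.

The renderer (`render_fusion_frames()`) draws rigid intersecting disks
whose centre distance reproduces the requested neck through the
circle–circle chord relation. No volume conservation or shape relaxation
is modelled: the synthetic stack matches exactly the quantities the
measurement stage extracts ($r_0$, lobe radii) and nothing more. Frames
whose model neck exceeds the smaller lobe radius (late fusion, where the
two-disk geometry degenerates) render as a single fused disk, which the
measurement stage then reports as `"neck undefined"` — mirroring how real
late-fusion frames drop out of the analysis.

## Nanoindentation: Hertz and Ting under power-law rheology

The elastic reference is Hertzian spherical contact,
$F = \tfrac{4}{3}\tfrac{E}{1-\nu^2}\,\delta^{3/2}\sqrt{R}$, fitted over
$\delta \in (0, 0.1R]$ (900 nm for the 9 µm tip) where the parabolic
approximation of the sphere holds; $\nu = 0.5$ for incompressible soft
tissue. The force is linear in $E$, so the estimate and its standard
error come from a regression through the origin on $\delta^{3/2}$.

The viscoelastic model is power-law rheology (PLR),
$E(t) = E_1 t^{-\alpha}$: two parameters cover the relaxation of soft
biological matter over the experimental window, with $E_1$ the modulus at
1 s and $\alpha$ the fluidity ($\alpha = 0$ elastic solid). Ting's
solution extends Hertzian contact to viscoelastic materials over a full
load–dwell–retract cycle: while the contact grows,

$$F(t) = \frac{4\sqrt{R}}{3(1-\nu^2)} \int_0^t E(t-\xi)\,
\frac{\partial \delta^{3/2}}{\partial \xi}\, d\xi,$$

and during retraction the upper limit is replaced by the auxiliary time
$t_1(t)$ at which $\int_{t_1}^{t} E(t-\xi)\,\dot\delta(\xi)\,d\xi = 0$,
with $t_1$ non-increasing in $t$.

**Numerics.** The kernel $(t-\xi)^{-\alpha}$ is weakly singular at
$\xi = t$, so each interval's contribution is integrated analytically
against a piecewise-linear $\delta^{3/2}$ — no pointwise kernel
evaluation at zero lag ever occurs, and $E(0)$ (singular for
$\alpha > 0$) is never needed. One refinement matters: $\delta^{3/2}$ has
unbounded curvature where $\delta \to 0$, and a plain per-sample
quadrature leaves percent-level errors at the first post-contact samples.
Intervals with depth below 5% of the peak are therefore subdivided on an
internal, cubically graded grid (exact for the piecewise-linear depth)
before quadrature. With this, the solver matches the closed-form ramp
solution
$F(t) \propto E_1 v^{3/2} \tfrac{3}{2} B(3/2, 1-\alpha)\, t^{3/2-\alpha}$
to better than $10^{-3}$ relative error for $\alpha \le 0.3$ at 250
samples, reproduces Hertz exactly at $\alpha = 0$, and changes by less
than $10^{-5}$ of peak force when the time step is halved. Because
$\dot\delta$ is exactly piecewise constant, Ting's $t_1$ condition is
analytic within each interval; the root is bracketed by an interval walk
and solved in closed form, with the non-increasing property enforced.
When the condition has no root the contact is fully lost and the force is
zero from then on. The solver is implemented in C++ because the inversion
evaluates it hundreds of times per curve.

**Inversion.** `fit_plr()` minimises force residuals of the forward model
over the complete post-contact curve. The force is linear in $E_1$, so
$E_1$ is profiled out in closed form and the search is one-dimensional in
$\alpha$, multi-started at 0.05, 0.2 and 0.4 and refined by bounded
golden-section search on $[0, 0.95]$; boundary solutions ($\alpha = 0$)
are accepted, where the estimate coincides with the Hertz modulus to
better than 0.5%. On noiseless synthetic cycles the inversion recovers
both parameters to $10^{-3}$ relative error; with 1% force noise on the
standard protocol, $E_1$ is recovered to well under 5% and $\alpha$ to
within 0.03.

**Contact point.** The detector is a two-segment fit — flat baseline plus
Hertzian $\delta^{3/2}$ rise — over all candidate split points, followed
by continuous sub-sample refinement; it refuses curves without a
pre-contact baseline and declares `"no contact"` when the post-split rise
is under three baseline noise standard deviations. On elastic curves
(the detector's own model) the contact is located to within two samples
at 0.1 nN noise. On PLR curves the early force rises as $t^{3/2-\alpha}$,
slightly steeper than the elastic model, which shifts the apparent
contact a few hundred nanometres early regardless of noise; this is an
inherent property of Hertz-model contact detection on viscoelastic
material, small relative to the 3.5 µm working depth.

Dwell is modelled as depth-controlled. Piezo-held instruments creep
slightly during dwell through cantilever compliance;
`compliance_correct()` converts piezo coordinates to indentation
($\delta = z - F/k$, with $k \approx$ 0.041–0.05 N/m for soft-tissue
probes) as an optional pre-processing step, off by default because the
synthetic curves are already in indentation coordinates.

## Tissue-level quantities and statistics

The surface tension of a spheroid scales with the stiffness of its
tensed surface layer, $\Gamma \sim E R_0$. This is an
order-of-magnitude estimator — the package tags it as such in every
output — and it feeds the apparent viscosity
$\eta = \Gamma / (\Gamma/\eta)$, reported in Pa·h with the µm/h → m/h
conversion handled internally. By construction the composition
`apparent_viscosity(surface_tension_estimate(E, R0), visco_capillary_velocity(tau, R0))`
collapses to $E\tau/2^{2/3}$ exactly, which is unit-tested as an
algebraic identity. Group-level values use group-mean moduli and radii,
so one viscosity per group; heterotypic pairs, whose two lobes have
different tensions, get no single viscosity.

`group_compare()` runs per-group Shapiro–Wilk and Pearson chi-square
normality tests, one-way ANOVA and Bonferroni-corrected pairwise t tests
(pooled SD), flagging adjusted p-values below 0.001. Calibration is part
of the test suite: the type-I error rate at nominal 0.05 over 1000 null
simulations, and near-certain power at the stiffness contrast typical of
epithelial versus mesenchymal spheroids (1.63 ± 0.34 vs ≈3.9 ± 0.8 kPa,
n = 20).

## The synthetic generators

The generators define the study conditions the tests run under:

- **Fusion** (`simulate_fusion_series()`, `generate_cohort()`): the
  9-point imaging schedule 0.5, 1, 2, 3, 4, 6, 7, 24, 48 h; cohorts of 12
  pairs; per-spheroid radii drawn from a truncated normal (default
  100 ± 20 µm, matching the 30–120 µm range of typical pairs); a common
  ground-truth visco-capillary velocity converted to per-pair $\tau$
  through the coalescence relation. Measurement noise is mean-one
  lognormal, multiplicative on $r_0$, with CV 0.05 by default. The CV is
  an assumption, not a measured quantity: manual neck measurements on
  stereomicroscope images plausibly carry a few percent relative error,
  and 5% is a deliberately conservative choice. Compaction of young
  spheroids is modelled as linear fractional shrinkage (clamped at 10% of
  the initial radius) because no functional form for compaction is
  established; it is off by default.
- **Imaging**: binary silhouettes only — no intensity texture, blur or
  illumination gradients. Passing the imaging round-trip therefore shows
  the geometry pipeline is correct, not that segmentation is robust to
  real microscope contrast.
- **Indentation** (`simulate_indentation_curve()`): the standard protocol
  (3.5 µm depth at 3.5 µm/s, 1 s dwell, symmetric retract, 9 µm tip,
  $\nu = 0.5$, 5 ms sampling), forces from the same Ting solver the
  inversion uses, additive Gaussian force noise applied last, optional
  pre-contact baseline for contact-detection tests. Because generator and
  inversion share the forward model, noiseless recovery tests are
  self-consistency checks; the *independent* evidence for the solver is
  the Beta-function ramp oracle, the elastic limit and the grid-halving
  test.

Per-object seeds are derived from a master seed by a counter-based linear
scheme, so cohorts are reproducible element-wise and any single trajectory
can be regenerated in isolation.

**Problem sizes.** The Monte-Carlo calibrations use 200 fusion series,
25 cohorts of 12 pairs, 100 indentation curves, 50 imaging geometries,
1000 null ANOVA simulations and 200 power simulations — sizes at which the
binomial uncertainty of the reported rates is a few percent, adequate for
the pass bands they are checked against.

## Known limitations

- The coalescence fit yields *effective* parameters; for matrix-rich
  spheroids the liquid-drop assumptions fail late in fusion and no
  elasto-visco-plastic alternative is provided.
- $\Gamma \sim E R_0$ is an order-of-magnitude estimate; downstream
  viscosities inherit that status.
- The imaging stage handles a single doublet per field, bright-field
  silhouettes only; no fluorescence, no 3-D reconstruction, no
  multi-object scenes.
- PLR is the only relaxation law offered; multi-exponential (Prony)
  models are out of scope as they need more parameters than these
  protocols can constrain.
- Contact detection on strongly viscoelastic curves carries a small
  systematic early shift (see above); when sub-100-nm contact accuracy
  matters, an elastic-dominated (fast) approach segment is the better
  experimental remedy.
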