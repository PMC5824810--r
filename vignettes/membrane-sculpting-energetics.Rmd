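---
title: "Models and methods: scaffold-driven membrane sculpting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: scaffold-driven membrane sculpting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsculpt)
```

`memsculpt` quantifies whether a curved scaffold bound to a lipid membrane
can remodel it. The chain has four quantitative legs — how strongly the
scaffold binds (Langmuir isotherm), how many scaffolds sit on the membrane
(FCS surface densities), what bending the scaffold's shape would demand
(ADE energetics), and what the vesicles actually do (morphology
statistics) — plus a synthetic-data generator that makes the whole chain
testable with known ground truth. This vignette documents the models, the
parameter choices, and the places where the design was genuinely open.

## Scaffold geometry

A scaffold is an arc of contour length $L$ (110 nm for the designs bundled
in `default_scaffolds()`) subtending angle $\theta$, so the arc-derived
radius is $R_{\mathrm{arc}} = L/\theta_{\mathrm{rad}}$ and the curvature is
$C = 1/R$. We deliberately store *two* radii per design: the arc-derived one
and the radius measured directly on electron micrographs. They disagree by
3–5% (e.g. 86.3 nm arc-derived vs 84 nm measured for the quarter-circle
design; 48.1 vs 46 nm for the semi-circle), and derived quantities —
curvature, predicted tube diameter $2R$ — key off the **measured** radius
when present, because that is the radius the scaffold actually imposes on a
membrane. Note the two conventions give visibly different curvatures for
the quarter-circle: $1/84\,\mathrm{nm} = 11.9\,\mu\mathrm{m}^{-1}$ while
$\theta/L = 11.6\,\mu\mathrm{m}^{-1}$; both are exposed rather than
silently reconciled.

Reporting conventions: tube diameters round to the nearest 10 nm, coverage
fractions ($\sigma A$, density times footprint) to integer percent. At the
densities where tubulation starts and saturates (50 and 90 particles per
µm² with a 1800 nm² footprint) coverage is 9% and 16% — the same regime
reported for BAR-domain proteins.

## Langmuir binding isotherm

Equilibrium membrane-bound intensity versus bulk concentration follows
$I = I_{\max} / (1 + K_d / C_{\mathrm{bulk}})$: half-saturation at
$C_{\mathrm{bulk}} = K_d$, saturation at $I_{\max}$. `fit_langmuir()` fits
by unweighted least squares (Levenberg–Marquardt) **in log-parameter
space** $(\log K_d, \log I_{\max})$, which enforces positivity without
constraints; reported standard errors are delta-method back-transforms.
Initialisation is deterministic — $I_{\max}$ from the 95th intensity
percentile, $K_d$ from the concentration nearest half of it — so repeated
fits are bit-identical. Per-GUV points are pooled by default; a
`per_concentration` mode averages GUVs per concentration first (the
pooling choice is not dictated by the assay, so both are provided), and
independent titration repeats can be fit separately and summarised as mean
± s.d. of $K_d$ via `fit_langmuir_repeats()`. Titrations spanning less than
a 4-fold concentration range trigger a warning: $K_d$ is then barely
constrained.

## FCS densities

Membrane FCS on the vesicle pole yields an autocorrelation curve fitted by
the bare one-component 2D model $G(\tau) = \frac{1}{N}\,
\frac{1}{1+\tau/\tau_D}$ — no triplet or photophysics terms, appropriate
for slow, bright, pre-bleach-controlled particles. The amplitude gives the
particle number $N$ in the detection area and the half-decay lag gives
$\tau_D$. Fitting mirrors the Langmuir fitter: log-parameter
Levenberg–Marquardt with deterministic initialisation ($N$ from the first
amplitude, $\tau_D$ from the half-amplitude lag). Flat, negative-amplitude
or too-short curves are rejected with diagnostics.

The detection-area waist comes from a reference dye of known diffusion
coefficient via $\tau_D = r_0^2/(4D)$; the dye's $D$ (414 µm²/s at 25 °C
for Alexa488) is moved to the working temperature by Stokes–Einstein
scaling $D_2 = D_1 (T_2/T_1)(\eta_1/\eta_2)$ with water viscosity from the
standard Vogel-type correlation anchored at 1.002 mPa·s at 20 °C (valid
15–40 °C; at 25→27.5 °C this gives 441.5 µm²/s). Absolute density is then
$\sigma = N/(\pi r_0^2)$ and the reduced density $\rho = \sigma L^2$ with
the scaffold length $L$ as a configurable constant, not a hard-coded
number. FCS densities are flagged invalid above the crowding cutoff
$\rho > 0.2$, where the one-component model underestimates density;
$\rho = 0.2$ exactly is kept valid to match the strict-inequality form of
the rule. In the crowded regime densities come instead from the
intensity→density calibration line (`build_intensity_calibration()`,
ordinary least squares through valid-regime pairs only; crowded pairs are
dropped and counted).

## ADE bending energetics

The Area-Difference-Elasticity energy of a uniformly curved patch of area
$A$ is

$$\varepsilon = \kappa\left[\frac{A}{2}(C_1+C_2-C_0)^2 +
\frac{\alpha}{2}\frac{\pi}{AD^2}(\Delta A - \Delta A_0)^2\right]$$

with bending modulus $\kappa = 23.1\,k_BT$ (DOPC), spontaneous curvature
$C_0 = 0$ (symmetric bilayer), thickness $D = 4$ nm, non-local ratio
$\alpha = 3/\pi$, and leaflet area difference $\Delta A$. For a cylinder of
radius $R$ the leaflet separation produces $\Delta A = DA/R$ — we take the
full bilayer thickness as the leaflet mid-surface separation; this is the
convention that reproduces the published tube energies, and the final
result does not depend on it — under which the energy collapses to

$$\varepsilon_{\mathrm{tube}} = 2\kappa A/R^2,$$

independent of $D$ (it cancels between the curvature and area-difference
terms). At the bundled parameters this gives 11.8 $k_BT$ for the
moderate-curvature scaffold footprint (1800 nm², R = 84 nm), 39.3 $k_BT$
at R = 46 nm, and 8.8 $k_BT$ for an amphiphysin-scale patch (23 nm²,
R = 11 nm). The closed form is verified in the tests against numerical
quadrature over a discretised cylinder with the leaflet areas measured on
the two offset surfaces, to 1e-6 relative. Note the 39.3 $k_BT$ sits a few
percent above the commonly quoted "~38": the rounding path behind that
printed value is not recoverable, so we keep the exact closed form and
accept a 10% comparison window.

Adhesion free energy uses $\Delta G = \ln(K_d/c^\circ)\,k_BT$ at standard
state $c^\circ = 1$ M — the standard state is forced by the requirement
that nanomolar $K_d$ values map to the −20 to −21 $k_BT$ range. The
cost–benefit rule `cost_benefit()` permits tubulation when
$|\Delta G| \ge \varepsilon_{\mathrm{tube}}$; equality counts as permitted
(an arbitrary but fixed and tested tie-break). Patches are treated as
independent — no scaffold–scaffold cooperativity, no global vesicle shape
minimisation.

## Morphology statistics

Per-GUV outcomes use a closed, case-normalised vocabulary (spherical,
outward/inward tubules, evagination/invagination, flaccid, burst); burst
vesicles stay in the denominator. Fractions carry Wilson score intervals
(default 95%) — preferable to Wald at the small per-condition counts
typical of GUV experiments. `threshold_density()` finds the smallest
density whose tubulated fraction reaches a target, linearly interpolating
after isotonic regression: measured fraction-vs-density curves can be
non-monotone from sampling noise while the underlying response is
physically monotone. Tube cross-section diameters are summarised as mean ±
sample s.d. and compared with the $2R$ prediction as a ratio.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the *structure* of the study conditions with
defaults mirroring its reported values: titrations at 8 concentrations
spanning 0.01–50 nM with ~15 GUVs each and true $K_d$ = 0.68 nM;
autocorrelation curves with $N = 12$, $\tau_D$ = 20 ms on an 80-point,
5-decade log-lag grid; a logistic density→tubulation link
$P = 1/(1+(\sigma_{50}/\sigma)^h)$ with $\sigma_{50} = 62$ µm⁻² and
$h = 4$ (placing the 80% point near 88 µm⁻², consistent with
near-complete tubulation at ~90 µm⁻²); and tube cross-sections drawn as
Normal(220, 70) nm, n = 35.

The noise models are declared conventions, not measured ones: mean-one
multiplicative lognormal noise (CV 0.2) on intensities, additive Gaussian
noise (s.d. 0.002) on $G$, Bernoulli draws for morphology. Real data add
vesicle-to-vesicle heterogeneity, correlated noise along FCS lag channels,
intensity baselines and segmentation artefacts — so passing recovery tests
demonstrates the estimators are correct and well-conditioned under the
stated noise, not that they are robust to every experimental pathology.
All generators are seeded through a single integer and are reproducible
draw-for-draw.

Problem sizes used by the test-suite recovery studies (200 replicates of
120-point titrations and 80-point curves) keep the full suite to a few
seconds while giving recovery-rate estimates with ~±3% Monte-Carlo error;
the rates (≥95% required) were calibrated with this same oracle before
the thresholds were frozen.

## Numerical choices and limitations

* All fits are deterministic given the data: no random restarts.
* Lengths are nm internally; curvature converts to µm⁻¹ only at the
  reporting boundary; energies are $k_BT$ throughout
  (`kBT_to_joule()` converts at a configurable temperature, default
  298.15 K).
* Degenerate inputs fail loudly: single-concentration titrations, all-zero
  intensities, flat correlation curves, unknown morphology labels, < 3
  valid calibration pairs.
* The viscosity correlation is only honoured on 15–40 °C; outside it the
  temperature correction errors rather than extrapolating.
* The package consumes pre-extracted tables (intensities, correlation
  curves, morphology calls); image segmentation and raw photon-trace
  correlation are upstream and out of scope, as are vesicle-shape phase
  diagrams and scaffold–scaffold interaction models.
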