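---
title: "Modelling liposome synthesis in a periodic-disturbance micromixer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling liposome synthesis in a periodic-disturbance micromixer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmix)
```

## The system being modelled

Liposomes — lipid bilayer vesicles of roughly 20 nm to 2 µm — form by
nanoprecipitation when an ethanol stream carrying dissolved lipids meets an
aqueous stream and the solvents mix. In a microfluidic mixer the two streams
merge at a Y-junction and travel down a mixing channel; how fast and how
uniformly the ethanol fraction drops controls the size and polydispersity of
the vesicles that self-assemble. The device treated here is a
periodic-disturbance mixer: a 300 µm × 300 µm channel, 47.5 mm long, carrying
90 semicircular wall obstacles of 260 µm radius whose centre of curvature
alternates side to side, squeezing the flow through 40 µm gaps and flipping
the centripetal force direction once per obstacle.

Two process factors are controlled by the syringe pumps:

* **TFR** (total flow rate, mL/h) — the sum of the two inlet flows;
* **FRR** (flow rate ratio) — aqueous:organic flow ratio, `Q_as / Q_os`.

The inlet flows follow from `Q_as = FRR·TFR/(1+FRR)` and
`Q_os = TFR/(1+FRR)` (`split_flows()`). Three responses are measured per run:
the intensity-weighted hydrodynamic diameter (Z-average, nm), the
polydispersity index (PDI), and the zeta potential (mV).

## Experimental design

The factor space is screened with a two-factor central composite rotatable
design (`build_cccr_design()`): `2^k` factorial ("cube") points at coded ±1,
`2k` axial points at ±α with `α = (2^k)^{1/4} ≈ 1.41` for `k = 2`
(`compute_alpha()`), and a replicated centre. Rotatability places cube and
axial points at the same coded distance from the centre, so the prediction
variance depends only on that distance.

Two conventions matter for reproducing the study's numbers and are therefore
fixed in the package:

* **The stated factor ranges are the axial extremes.** FRR 1.0–12.0 and TFR
  3.0–18.0 mL/h sit at coded ±α; the cube levels are derived inside them as
  `centre ± half_range/α`, giving FRR {2.6, 10.4} and TFR {5.2, 15.8}. This
  is what reproduces the measured run table exactly, even though the design's
  name ("circumscribed") would normally suggest the opposite convention; the
  package reproduces the numbers and leaves the nomenclature question open.
* **Pump-realisable rounding.** Natural settings are rounded to 0.1 (the
  syringe-pump resolution) *before* being stored, and every later fit uses
  these rounded values — they are what the pumps actually delivered.

The replication scheme (3× cube, 3× axial, 5× centre) yields 29 runs over 9
distinct conditions; the run order is randomised by a seeded uniform
permutation recorded in the design metadata.

## Response-surface models

For each response a quadratic surface

\[ y = b_0 + b_1\,\mathrm{FRR} + b_2\,\mathrm{TFR} + b_{11}\,\mathrm{FRR}^2
   + b_{22}\,\mathrm{TFR}^2 + b_{12}\,\mathrm{FRR}\cdot\mathrm{TFR} \]

is fitted by ordinary least squares (`fit_quadratic()`, natural units) and
reduced by backward elimination (`reduce_model()`): the least significant
removable term with partial *p* above the threshold is dropped and the model
refitted until all surviving terms clear it. Term *p*-values are partial
(type-III) tests, identical to the coefficient *t*-tests for OLS. Hierarchy
is respected: a main effect is never removed while its square or an
interaction containing it survives.

The removal threshold defaults to **α-to-remove = 0.1**, the standard
backward-elimination convention. The choice is substantive: on the measured
data the TFR term of the reduced PDI model has *p* ≈ 0.062, so a strict 0.05
rule would evict TFR and change the published model; the 0.1 rule removes
exactly the two second-order terms (TFR² and FRR·TFR) from both the size and
PDI models and reduces the zeta model to the intercept, reproducing the
study's endpoints. Overall model significance is still reported against the
0.05 F-test.

Goodness of fit (`goodness_of_fit()`) reports the R² trio. Predicted R² is
PRESS-based: with leverages `h_ii`, `PRESS = Σ (e_i/(1-h_ii))²` and
`R²_pred = 1 − PRESS/SST`, floored at zero for reporting (the raw value is
kept). `predict()` returns the mean prediction with
`SE_fit = sqrt(xᵀ Σ_b x)` and a Student-t confidence interval for the mean;
a prediction interval for a single future observation is returned alongside,
because both conventions circulate. The published interval at the size
optimum matches the confidence-of-mean version, which is therefore the
headline `ci`.

`optimize_response()` minimises or maximises a fitted surface over the
rectangular experimental region in closed form: the clamped unconstrained
stationary point, the stationary points of the four edge restrictions, and
the corners are enumerated and the best evaluated candidate returned with
boundary flags. For the size model the minimum sits at the interior FRR
stationary point `-b_1/(2 b_{11})` with TFR pushed to its upper bound.

## Comparing design conditions

`tukey_groups()` runs all pairwise Tukey–Kramer tests on the pooled
within-condition variance (`q = |m_i − m_j| / \sqrt{(s²/2)(1/n_i + 1/n_j)}`
against the studentised range with `N − g` df; with equal replication this is
exactly the classic Tukey HSD) and assigns a compact letter display by the
insert-and-absorb algorithm in order of descending mean. On the measured PDI
data this produces three letter classes with the (FRR 1.0, TFR 10.5)
condition isolated at mean 0.07 — the low-FRR regime producing nearly
monodisperse vesicles — while the zeta potential conditions share a single
letter, i.e. the model-free confirmation that neither factor moves zeta
potential. A zero pooled variance degenerates to grouping by exact equality,
reported via a message rather than an error.

`paired_t()` is the stability test (size or PDI before vs months after
production). The six-month measurements are not available as numbers, so the
package exercises the test on synthetic data only; the published stability
claim is a documentation note, not an assertion.

## The desk-scale mixing simulator

The published mixing analysis solved the full three-dimensional
Navier–Stokes and convection–diffusion equations in commercial software.
This package deliberately implements a *desk-scale planar* reduction — the
mid-depth 2-D footprint — because the aim is a reusable, testable model of
the mixing *behaviour* (what grows, what orders, what saturates), not a
bit-for-bit CFD replica. Everything asserted about the simulator is
property-based for exactly that reason.

**Flow** (`solve_flow()`): steady creeping flow in streamfunction–vorticity
form, `∇²ψ = −ω`, `∇²ω = 0`, assembled dimensionless (lengths by the channel
width, ψ by the planar flow rate) into one sparse linear system and solved
directly. At the device's Reynolds numbers (about 6–20 across the TFR range)
inertia is a secondary effect, and dropping it makes the flow linear in the
flow rate — a property the tests assert — and independent of FRR, so one
flow solve serves every FRR at a given TFR. No-slip enters through the wall
vorticity closure: Jensen's second-order formula where two fluid neighbours
exist along the wall normal, Thom's first-order formula otherwise. Walls are
discretised as cell staircases; a node is solid only when all four adjacent
cells are solid, which guarantees that every face between a fluid and a
blocked cell carries exactly zero streamfunction difference — discrete mass
conservation then holds to solver precision by construction.

**Transport** (`solve_transport()`): finite-volume advection–diffusion of
the normalised ethanol fraction `c ∈ [0, 1]`, with face fluxes taken directly
as streamfunction differences (exactly divergence-free). Convection is
first-order upwind plus a deferred-correction van Leer (TVD) term iterated to
a fixed point on a single LU factorisation, under-relaxed (0.8) to damp
limiter cycling. The upwind operator keeps the solution bounded; the
correction removes most of the streamwise numerical smearing, without which
the profile was found to mix unphysically fast and identically for every FRR.
Inlet composition is `c = 1` below the streamline carrying the organic flux
fraction `1/(1+FRR)`, `c = 0` above; outflow is convective. Property
coupling is sequential by default (diffusivity at the fully mixed reference
composition `1/(1+FRR)`); `coupling = "picard"` iterates the
concentration-dependent diffusivity to a fixed point. The flow solve always
uses reference-composition properties — in creeping flow with uniform
viscosity the velocity field is set by the flow rate alone, so this is a
statement about viscosity-gradient effects being neglected, not an
approximation of convenience. Iteration caps raise an explicit
non-convergence error carrying the residual history.

**Properties**: packaged 25 °C water–ethanol tables (density, viscosity,
mutual diffusivity versus ethanol mass fraction; literature-derived
representative values, documented in the fixture header) fitted with
order-5 polynomials (`property_model()`), checked positive on [0, 1] and
against the pure-component entries within 1%. A `dispersion_factor`
multiplier on the diffusivity is available to emulate transverse stirring by
out-of-plane secondary (Dean-type) flow that a planar model cannot resolve.
Its default is 1: at the working resolution the staircase representation of
the obstacles already contributes transverse dispersion above molecular, and
adding more was found unnecessary for any qualitative behaviour. The profile
should accordingly be read qualitatively.

**Mixing efficiency** (`mixing_profile()`): at stations along the channel the
cross-section is sampled at 50 transverse points (the published 50 × 50
section grid degenerates to a 50-point line in 2-D; the parameter is kept for
interface compatibility) and the Danckwerts intensity of segregation gives
`ME = (1 − σ²/σ₀²) × 100%`, with σ₀² the variance of the fully segregated
entry section. ME is clamped to [0, 100]. `distance_to_threshold()`
interpolates the profile linearly (anchored at ME = 0 at the entry) and
returns a censored result, not an error, when the threshold is never
reached. `transverse_nonuniformity()` summarises profile uniformity as the
coefficient of variation of the section samples.

What the planar model reproduces, and the tests assert: plane-Poiseuille flow
in a straight channel within 2%; mass and species conservation below 1e-6
relative; the two-stream transverse diffusion series within 2%; ME rising
monotonically along the channel; the 90%-mixing distance non-increasing in
FRR at fixed TFR (the narrower the organic stream, the faster transverse
dispersion homogenises it); and less uniform transverse profiles at higher
FRR. What it cannot reproduce: three-dimensional Dean vortices, absolute
mixing lengths comparable to the 3-D analysis, and any link from mixing to
liposome size — no such mechanistic equation exists to implement.

**Problem sizes.** The default study discretises the 300 µm width with 30
cells (10 µm cells, 4 across the narrowest gap — the enforced minimum) and
square cells along the channel, about 47 000 fluid cells for the full
47.5 mm device; the flow solve takes a few seconds and each transport solve
a few tens of seconds on one core. Unit tests exercise the same code on
shorter sections of the identical cross-section. Station counts default to
10 per profile (mirroring the published figure) and to roughly one per
obstacle in `mixing_study()`, where the threshold crossing must be resolved.

## The synthetic-data generator

`generate_run_table()` emulates the statistical structure of the measured
table so that every downstream stage can be tested against a known truth:
size and PDI are drawn from the study's fitted reduced surfaces (the
defaults of `truth_spec()`) plus homoscedastic Gaussian replicate noise, and
zeta potential is factor-independent Gaussian. Defaults: size SD 6 nm — the
mid-range of the replicate SDs observed in the measured data (0.43 to
11.48 nm); PDI SD 0.02 and zeta −31.5 ± 4 mV, matching the measured
replicate spread. PDI is clipped into (0, 1) with clip events reported.
`generate_validation_sweep()` reproduces the validation layout: triplicates
along an FRR list at fixed TFR.

The generator emulates the *noise structure*, not the chemistry: it is
homoscedastic where real replicate SDs varied 25-fold, it has no
batch-to-batch lipid effects, no bubbles, and no departures from the
quadratic surface (the real size curve plateaus at high FRR, which a
quadratic cannot). Passing recovery tests therefore demonstrates that the
estimation machinery is correct and calibrated — nominal CI coverage,
correct term selection, SD envelope — and nothing about how liposomes behave
beyond the fitted surfaces.

## Numerical and design choices

* Printed-value comparisons in tests use 1% relative tolerance: published
  values are rounded, and the factor settings feeding them are 1-dp rounded.
* α is reported at 2 decimals (1.41) but used at full precision internally.
* Condition means in Tukey tables are rounded to 2 decimals for display;
  full-precision means are kept as an attribute.
* The degenerate inputs each operation may face (zero pooled variance, zero
  within-pair variance, unmixed inlet with σ₀² = 0, leverage 1, singular
  designs, censored thresholds) are signalled with classed conditions —
  `pdmix_invalid_argument`, `pdmix_singular_design`, `pdmix_nonconvergence`,
  `pdmix_undefined_me`, `pdmix_press_undefined` — so callers can distinguish
  them programmatically.
* Run-order randomisation and all generators draw from a private RNG stream
  seeded explicitly; the caller's RNG state is never perturbed.

## Known limitations

* The quadratic surface family cannot represent the high-FRR size plateau;
  extrapolation beyond the design region warns and should not be trusted.
* The planar simulator underestimates absolute mixing lengths and carries
  grid-orientation dispersion from the staircase walls; only ordering and
  monotonicity statements are supported.
* The backward-elimination endpoint depends on the α-to-remove convention
  (see above); both the threshold and the starting term set are arguments.
* Tukey letters are a summary of the pairwise test matrix, which is also
  returned; letters from small replicate counts (n = 3) are sensitive to
  single observations.
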