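---
title: "A coupled immune/hydro-mechanical model of inflammatory myocardial edema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled immune/hydro-mechanical model of inflammatory myocardial edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`poroedema` simulates how an infection of the heart muscle produces a
localized accumulation of interstitial fluid — an inflammatory edema — by
coupling three sub-models on a common 2D triangular mesh of the ventricular
wall.

**Immune dynamics.** The pathogen concentration $C_p$ (in $10^{10}$
cell/cm$^3$) and leukocyte concentration $C_l$ (in $10^{7}$ cell/cm$^3$)
live in the interstitial fluid, which occupies the porosity fraction
$\phi_f$ of the tissue:

$$\phi_f \frac{\partial C_p}{\partial t}
  = \nabla\cdot(D_b \nabla C_p) + c_p C_p - \lambda_{nb} C_l C_p,$$

$$\phi_f \frac{\partial C_l}{\partial t}
  = \nabla\cdot(D_n \nabla C_l - \chi_{nb} C_l \nabla C_p)
  + \gamma_n C_p (C_{n,max} - C_l) - \lambda_{bn} C_l C_p - \mu_n C_l,$$

with zero (total) flux on the whole boundary.  The pathogen reproduces at
rate $c_p$ and is phagocytosed by leukocytes; leukocytes extravasate from
the blood (saturating at the blood concentration $C_{n,max}$), move
diffusively and chemotactically up the pathogen gradient, and die by
apoptosis.  With the default rates the two populations settle into
coexistence: phagocytosis ($\lambda_{nb} C_l \approx 0.15$/h once
$C_l \approx 0.09$) almost exactly balances reproduction
($c_p = 0.15$/h), which is the regime in which a persistent inflamed
region forms.

**Interstitial flow.** The interstitial pressure $P$ (mmHg) obeys a
parabolic balance whose storage coefficient comes from the poroelastic
moduli,

$$S\,\frac{\partial P}{\partial t} = \nabla\cdot(k \nabla P) + q_c + q_l,
 \qquad S = \frac{3}{3\lambda_s + 2\mu_s},$$

with capillary filtration (Starling law) on the capillary elements,

$$q_c = L_p(C_p)\,\frac{S_c}{V}\,\bigl(P_c - P - \sigma(C_p)(\pi_c - \pi_i)\bigr),
\qquad L_p = L_{p0}(1 + c_{bp} C_p),
\qquad \sigma = \frac{\sigma_0}{1 + c_{br} C_p},$$

and Hill-type lymphatic drainage on the 2.9% of elements occupied by lymph
vessels,

$$q_l = -q_0\Bigl(1 + \frac{V_{max} (P-P_0)^n}{K_m^n + (P-P_0)^n}\Bigr).$$

Infection opens the microvascular wall ($L_p$ grows linearly in $C_p$ with
slope $c_{bp}$) and makes it leaky to plasma proteins ($\sigma$ decays),
so the local filtration equilibrium moves from the healthy
$P = P_c - \sigma_0(\pi_c-\pi_i) = 10.9$ mmHg toward the capillary
pressure $P_c = 20$ mmHg.  $c_{bp}$ is the coupling knob between the
immune and hydro-mechanical halves of the model.

**Poroelasticity.** The solid skeleton responds quasi-statically to the
pressure gradient,

$$(\lambda_s + \mu_s)\nabla(\nabla\cdot U) + \mu_s \nabla^2 U = \nabla P,
\qquad U = 0 \text{ on } \partial\Omega,$$

and the dilatation $e = \nabla\cdot U$ moves fluid into the pores:
linearizing the solid mass balance, $\phi_s = \phi_{s0}(1-e)$, so the
relative solid-phase decrease equals $e$.  The edematous region is
delineated by the isoline $e = 0.10$ (a 10% solid-phase decrease), and its
area — bounded by the isoline and the domain boundary — is the headline
output, comparable against an imaging-derived reference area via
`compare_areas()` (relative error normalized by the simulated area, the
convention that reproduces the published 1.56% from the printed pair
1.755/1.728 cm²).

## Signs and conventions

Two printed-source ambiguities are resolved as follows and are worth
stating explicitly.

* **Sign of the flow sources.**  We solve
  $S \partial_t P = \nabla\cdot(k\nabla P) + q_c + q_l$, i.e. capillary
  filtration pressurizes the tissue and lymphatic drainage relieves it.
  The opposite sign (sources on the left) would make the Starling term an
  anti-damping feedback: a linear-stability check shows the uniform state
  then diverges exponentially at rate $c_f/S$, incompatible with bounded
  reported pressure fields.  The chosen sign agrees with the mixture mass
  balance $\nabla\cdot v_D + \partial_t e = q_c + q_l$ with
  $v_D = -k\nabla P$.

* **Unit of the Lamé moduli.**  The moduli are reported as
  $\lambda_s = 27.293$, $\mu_s = 3.103$ "kPa".  Converting them
  dimensionally to the model's mmHg pressure unit gives
  $\lambda_s + 2\mu_s \approx 251$ mmHg, while the pressure is bounded
  above by $P_c = 20$ mmHg (maximum principle of the pressure equation:
  the Starling source vanishes at $P_c$ when $\sigma \to 0$ and is
  negative beyond).  Peak dilatation is then $\lesssim 20/251 \approx
  0.08$ — we measure 0.069 in the full scenario — and the 10% edema
  isoline encloses *identically zero* area, for any choice of the free
  parameters.  The published nonzero edema areas are mutually consistent
  only if the stiffness numerals act in the working pressure unit
  (mmHg), giving $\lambda_s + 2\mu_s = 33.5$ and peak dilatations around
  0.26.  `elastic_params()` therefore takes the moduli with an explicit
  `unit` argument; the reference scenario uses `unit = "mmHg"` (the
  as-printed reading), and `convert_units()` performs the exact
  dimensional conversion (× 7.50062) when `unit = "kPa"` is requested.
  The kPa reading remains available for sensitivity studies.

## Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| $\phi_f$ | porosity (fluid fraction) | 0.2 | – |
| $D_b$, $D_n$ | pathogen / leukocyte diffusivity | $5\times10^{-5}$ | cm²/h |
| $c_p$ | pathogen reproduction rate | 0.15 | 1/h |
| $\lambda_{nb}$ | phagocytosis rate | 1.8 | cm³/(h·10⁷cell) |
| $\chi_{nb}$ | chemotaxis rate | $10^{-4}$ | cm⁵/(h·10⁷cell) |
| $\lambda_{bn}$ | leukocyte death after phagocytosis | 0.1 | cm³/(h·10¹⁰cell) |
| $\gamma_n$ | leukocyte capillary permeability | 0.1 | cm³/(h·10⁷cell) |
| $C_{n,max}$ | blood leukocyte concentration | 0.55 | 10⁷cell/cm³ |
| $\mu_n$ | leukocyte apoptosis rate | 0.2 | 1/h |
| $P_c$, $\pi_c$, $\pi_i$ | capillary / oncotic pressures | 20, 20, 10 | mmHg |
| $L_{p0}$ | healthy hydraulic permeability | $3.6\times10^{-8}$ | cm/(s·mmHg) |
| $\sigma_0$ | healthy reflection coefficient | 0.91 | – |
| $c_{bp}$ (= $c_{br}$) | infection–permeability coupling | 60 | cm³/10¹⁰cell |
| $q_0$ | normal lymph flow | $10^{-4}$ | cm/s |
| $V_{max}$, $K_m$, $n$ | lymph Hill parameters | 20, 6.5 mmHg, 5 | – |
| $\lambda_s$, $\mu_s$ | Lamé moduli (as-printed reading) | 27.293, 3.103 | mmHg |

Two leukocyte concentration units ($10^{7}$) and pathogen units
($10^{10}$ cell/cm³) are implied by the units of the rate constants; with
those choices every reaction product is dimensionally consistent without
further scaling.  $C_{n,max}$ is reported as $0.55\times10^{7}$ cell
without a volume; we read it as per cm³.  The initial condition
$C_p = 0.2$ on the infected boundary strip carries no printed unit and is
read in the pathogen unit.

Four quantities the tables do not fix are exposed as calibration inputs
with physiologically motivated defaults, chosen once:

* `S_over_V` = 174 cm⁻¹, a typical myocardial capillary surface density.
* `mobility` $k = 3.6\times10^{-3}$ cm²/(mmHg·h).  The Darcy mobility of
  the interstitium is never reported.  This value makes the pressure
  diffusion length $\sqrt{k\,t/S}$ at 10 h (≈ 1 cm) comparable to the
  wall thickness — pressure equilibrates across the wall over the
  simulated horizon without flattening the infection-driven contrast —
  and keeps the dips at the lymph sinks to fractions of a mmHg (a 10×
  smaller mobility combined with strong single-element sinks produced
  −40 mmHg spikes, far outside the physiological interstitial range).
* `c_br` defaults to $c_{bp}$: the tables list a single coupling
  constant, the reflection-coefficient law names a second; tying them is
  the parsimonious reading and is overridable.
* `lymph_density`: the lymph law returns a wall *flux* (cm/h) while the
  mass balance needs a volumetric rate (1/h); the conversion factor — the
  lymph-vessel surface per tissue volume — is unreported.  With the
  element-scale density $1/\sqrt{A_e}$ (≈ 26 cm⁻¹) each lymph element is
  a strong point sink and the local pressure field is dominated by
  exactly where the random vessels landed (edema-area coefficient of
  variation ≈ 27% over 12 placements), incompatible with the documented
  insensitivity of the result to the lymph seed.  The default
  `lymph_density = 1` cm⁻¹ makes the lymph numerals act directly as
  volumetric rates (0.36/h normal, 7.6/h saturated) — weak, spatially
  benign sinks.  The strong-sink reading stays available via
  `lymph_density = NULL`.
* `capillary_everywhere = TRUE`: whether lymph elements also carry
  capillary filtration is ambiguous in the source description (the
  non-lymph elements are "only under capillary influence", which fixes
  nothing about the lymph elements).  Restricting filtration to the
  complement punches random holes into the infection-amplified Starling
  source, and even with weak sinks those holes move the edema area by
  ~18% across placements.  With filtration everywhere and drainage
  added on the lymph elements the *final* (10 h) area is insensitive to
  the lymph seed (CV ≈ 2.4% over 12 placements), as documented; that reading is the
  default, the partitioned one a flag.  Early-transient areas remain
  placement-sensitive under any reading — at 2 h the young edema is a
  thin marginal band and its area wobbles by ~15% across seeds — so the
  robustness statement is about the mature edema.
  Under these defaults the healthy tissue equilibrates near 6–8 mmHg,
  where saturating drainage on 2.9% of the elements balances Starling
  filtration everywhere.
* The Hill term is clamped to zero for $P < P_0$: the odd exponent would
  otherwise reverse the drainage for sub-normal pressures.

## Discretization

All fields use P1 (linear triangle) elements.  Time derivatives are
backward differences (backward Euler); each step advances, in order,
pathogen → leukocytes (seeing the new pathogen field) → pressure (new
pathogen field) → quasi-static displacement (new pressure), the one-way
coupling of the continuous model.  Reaction terms linear in the unknown
are implicit; cross-species factors are lagged one level, so every stage
is a single sparse linear solve and no Newton iteration is needed.

The time-derivative and reaction terms use *lumped* (nodal) mass: each
stage matrix is then an M-matrix wherever the transport term permits,
and the discrete maximum principle keeps concentrations non-negative
(observed minima in the reference run are of order $10^{-90}$, i.e.
exact zeros up to roundoff).  A consistent-mass variant produces
undershoots of order $10^{-4}$ near the discontinuous initial condition.
Uniform-field growth/decay closed forms
($C^1 = C^0/(1 \mp \Delta t\,r/\phi_f)$) hold exactly under either
quadrature and are asserted in the tests.

Chemotactic transport is advection with the element-wise velocity
$\chi_{nb}\nabla C_p$ and is stabilized with SUPG (streamline diffusion)
using
$$\tau_e = \frac{h_e}{2\lvert v_e\rvert}\,\min(1, \mathrm{Pe}_e/3),
\qquad \mathrm{Pe}_e = \frac{\lvert v_e\rvert h_e}{2D},$$
which vanishes in diffusion-dominated elements and reduces the operator
to plain Galerkin for zero velocity.  The Galerkin part is assembled in
conservative (integrated-by-parts) form, so the zero-total-flux boundary
condition is natural and the scheme conserves the discrete mass
functional to solver tolerance.  SUPG is not perfectly monotone: steady
transport at element Peclet 10 shows a residual crosswind wiggle below
0.5% of the jump, which is the origin of the small tolerance allowed on
field positivity.

The displacement equation is discretized in the grad-div + vector
Laplacian form as written above (`form = "grad_div"`); the variational
form based on the full symmetric stress
$\nabla\cdot(\lambda_s\,\mathrm{tr}\,\varepsilon\, I + 2\mu_s\varepsilon)$
differs at the discrete level for non-smooth fields and is available as
`form = "full_stress"` without guessing which the original authors used
(the two agree to a few percent on smooth pressure pockets).  The
pressure load enters as $(P, \nabla\cdot W)$; the elasticity operator is
factorized once (homogeneous Dirichlet data on the whole boundary) and
reused.  Because the displacement is quasi-static, memoryless and feeds
nothing back into transport or pressure, it is evaluated at output times;
the result is identical to solving it every step.
Dirichlet conditions are imposed by symmetric
elimination, so constrained values are exact and SPD structure is kept.
Linear systems are solved by sparse direct methods (CHOLMOD / sparse LU)
with a residual guard of $10^{-10}(\lVert b\rVert + 1)$.

Dilatation is computed element-wise from the P1 gradients and averaged
onto nodes with element-area weights only for isoline extraction; the
edema area itself is the exact area of the sub-triangle polygons where
the nodal interpolant exceeds the threshold (marching triangles with
polygon clipping), so it does not depend on counting whole elements.

## The synthetic geometry and what it does (not) represent

The patient-specific mesh behind the published study is not distributed,
so the package generates an annular-sector stand-in: a curved wall with
an endocardial and an epicardial boundary, default radii 2 and 3 cm,
opening angle $\pi$, target edge 0.055 cm (≈ 5 400 triangles ≈ the
reported 5 015).  Lymph vessels occupy 2.9% of the elements, placed
uniformly at random by seed; the infection starts as $C_p = 0.2$ on the
central fifth of the epicardial arc (the printed source does not state
the strip's extent; it is a configuration input).  The synthetic wall
preserves the structural features the model needs — thin curved domain,
clamped boundaries, epicardial infection, random lymph microanatomy —
but not the true long-axis anatomy, fiber structure, or the registration
with any MRI exam.  Consequently the absolute areas below are properties
of this geometry, not predictions of the patient case; what transfers
are the relational results (growth in time, monotone response to
$c_{bp}$, insensitivity to the lymph seed) and all of the numerical
verification.

## Verification

* **Closed forms.** Element mass/stiffness matrices against order-2
  Gauss quadrature; backward-Euler growth/decay; Starling baseline
  driving pressure 10.9 mmHg; lymph flow $-q_0$, $-11q_0$, $-21q_0$ at
  $P_0$, $P_0 + K_m$, $P\to\infty$; storage coefficient
  $4.541\times10^{-3}$ mmHg⁻¹ for the kPa moduli reading.
* **Oracle.** On a radially symmetric annulus (no chemotaxis, no lymph,
  diffusivity raised to 0.02 cm²/h so the 5 h profile is grid-resolved)
  the 2D solver matches an independent 1D conservative finite-difference
  solution to 0.6% (fields) and 0.02% (pressure) relative $L^2$.
* **Structure.** Mass conservation to $10^{-10}$ with sources off;
  positivity; exactness of Dirichlet data; permutation equivariance of
  assembly; second-order convergence of the elasticity solve on a
  manufactured solution; exact thresholded areas for linear fields.
* **Scenario properties.** Edema area strictly increasing over
  $c_{bp} \in \{40,\dots,80\}$; area at 10 h > area at 5 h; coefficient
  of variation over 12 lymph placements below 5%; displacement maxima at
  the border of the infected region rather than its center.

Problem sizes used by the test-suite: the reference runs use the
~5 400-triangle wall at $\Delta t = 0.01$ h (the default, which resolves
the fastest rate $c_p/\phi_f = 0.75$/h by two orders of magnitude;
halving it changes integrated concentrations by well under 2%); the seed
study repeats the full 10 h run twelve times; structural tests run on
meshes of a few hundred elements.

## Limitations

Two-dimensional, isotropic, small-strain; no fiber anisotropy and no
active contraction; the deformation does not feed back on the infection
model (one-way coupling); no blood-compartment hemodynamics or protein
transport; MRI segmentation and registration are out of scope — meshes
are read (Gmsh MSH), not derived from images.  The lymph surface-density
conversion and the Darcy mobility remain calibration inputs; conclusions
that depend on their absolute values should be re-examined against the
sensitivity interfaces (`sweep_cbp()`, `seed_sensitivity()`, and the
flagged fields of `flow_params()`).
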