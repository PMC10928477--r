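---
title: "A moving-boundary model of dendritic spine growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A moving-boundary model of dendritic spine growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

## The biological problem

Dendritic spines — the micrometre-scale protrusions that carry most
excitatory synapses — enlarge within minutes of a potentiating stimulus
(structural long-term potentiation, sLTP).  The enlargement is driven by
remodeling of the spine's actin cytoskeleton: a stimulus-triggered influx of
actin, the branching nucleator Arp2/3, and the severing protein cofilin
raises the density of polymerizing filament barbed ends, whose
polymerization against the membrane generates a protrusive force.
`spinesim` simulates this process in three dimensions with a moving
boundary: chemistry lives on a fixed cubic lattice, mechanics on a
triangulated membrane embedded in it, and the two are coupled through a
signed-distance field.

## Model

**Force balance.**  The membrane $\Gamma$ (enclosing the spine volume
$\Omega$) is overdamped: drag balances the bending force and the actin
polymerization force,

$$\omega \frac{d\Gamma}{dt} = \mathbf{F}_{\mathrm{mem}} +
\mathbf{F}_{\mathrm{actin}},$$

with drag coefficient $\omega$ (s·pN/µm) absorbing both fluid drag and
adhesion to the extracellular matrix.  $\mathbf{F}_{\mathrm{mem}} =
-\partial E_{\mathrm{mem}}/\partial \Gamma$ derives from the Helfrich
bending energy $E_{\mathrm{mem}} = \tfrac{\kappa}{2}\int_\Gamma H^2\,dA$
with zero spontaneous curvature.  We adopt the $H = c_1 + c_2$ (sum of
principal curvatures) convention, under which a sphere of any radius has
energy $8\pi\kappa$; this is the dominant convention in the membrane
literature and gives a sharp, testable constant.  Membrane tension and
osmotic pressure are deliberately absent: on the minutes timescale the
spine membrane area is unconstrained because of exo/endocytic membrane
addition.

**Membrane–chemistry coupling.**  Each lattice point $\mathbf{r}$ carries a
signed distance $d_s(\mathbf{r}, \Gamma)$ to the membrane (negative
inside), from which a soft repulsive potential

$$\psi = \frac{\alpha}{2}\tanh(\beta d_s)$$

and its force density $\mathbf{f}_u = -\nabla\psi = -\tfrac{\alpha\beta}{2}
\,\mathrm{sech}^2(\beta d_s)\,\mathbf{d}$ are built, where $\mathbf{d}$ is
the unit direction of increasing $d_s$.  The potential confines the
chemistry to the spine interior; symmetrically, the barbed-end energy
$E_B = \int_\Omega \psi(\mathbf{r},\Gamma) B(\mathbf{r})\,d\mathbf{r}$
yields the protrusive force $\mathbf{F}_{\mathrm{actin}} = -\partial
E_B/\partial\Gamma$ on the membrane.

**Species dynamics.**  The barbed-end density $B$ (ends/µm³) and the
Arp2/3 and cofilin concentrations $A, C$ (µM) obey

$$\partial_t B = -\nabla\cdot(\nu\,\mathbf{d}\,B) +
\eta\,\nabla\cdot(\mathbf{f}_u B) - k_\beta B +
\Psi_0 (f_{\mathrm{nuc}} + f_{\mathrm{sev}} + I_\beta + I_{S,\beta}),$$

$$\partial_t A = -\nabla\cdot(\xi\,\nu_{mp}\,\mathbf{d}\,A) - k_A A
- f_{\mathrm{nuc}} + I_A + I_{S,A}, \qquad
\partial_t C = -\nabla\cdot(\xi\,\nu_{mp}\,\mathbf{d}\,C) - k_C C
- f_{\mathrm{sev}} + I_C + I_{S,C},$$

with branching nucleation $f_{\mathrm{nuc}} = k_{\mathrm{nuc}} A \Psi_1 B$
(linear in both reactants, reflecting side-branching off existing
filaments) and cooperative severing $f_{\mathrm{sev}} = k_{\mathrm{sev}}
\frac{C^n}{k_n + C^n}\Psi_1 B$ (Hill kinetics, $n = 3.5$).  Both reactions
*consume* free Arp2/3 or cofilin while *producing* barbed ends — the
stoichiometric coupling the tests assert pointwise.  $\nu$ is the fixed
polymerization speed, $\nu_{mp}$ the measured protrusion speed of a tracked
membrane vertex (clamped at zero from below), and $\xi \in (0,1)$ slows the
bulk flow of the proteins relative to the membrane.  $\Psi_0$ and $\Psi_1$
convert between concentration and barbed-end count; they follow from
filament geometry — a 450 nm mean dynamic filament at 2.7 nm per monomer
gives 167 monomers per filament, a 37 nm minimal branch spacing gives 12
Arp2/3 per filament, so $\Psi_0 = 602.214/167 \approx 3.6$ and
$\Psi_1 = 12/602.214 \approx 0.02$ (`derive_scale_factors()` computes
both).

**Influx geometry and stimulus.**  The basal influx is spread uniformly
over the lattice points inside the spine head (fixed at run start); all
influx rates are divided by the number of basal locations so that the
domain totals match the well-mixed model.  The stimulus-triggered influx
is active for one minute per window, localized to interior points within
one lattice spacing of the membrane at heights z ∈ [0.7, 1.0] µm (under
the postsynaptic density, which stays put on this timescale), and scaled
by the initial head volume relative to a reference so the delivered dose
tracks the initial head size (in the default geometry the scale is 1).

## The non-spatial model and the fitting module

Influx and turnover parameters are constrained by a well-mixed reduction:
in normalized concentrations $b = \beta/\beta^*$ etc.,

$$\frac{db}{dt} = \frac{I_{S,\beta}(t)}{\beta^*} + k_\beta(1 - b),$$

so the pre-stimulus state $(1,1,1)$ is an exact fixed point.  We define
the basal influxes as $I = k \cdot (\text{steady state})$ to make that
fixed point exact; the dimensional parameter table is kept as data (its
$I_\beta/k_\beta = 3015.9$ µM differs from the quoted $\beta^* = 3000$ µM
in the fourth digit — rounding we do not silently repair).  The model is
piecewise linear, so `minimal_solution()` provides an exact
piecewise-exponential solution used both as the fitting backend and as an
independent cross-check of the `ode45`-style integrator in
`simulate_minimal()`.

`fit_minimal()` estimates $\{k_\beta, k_A, k_C, I_{S,\beta}, I_{S,A},
I_{S,C}\}$ by bounded trust-region least squares (`minpack.lm`), with
log-uniform multi-starts around the initial guess because the
six-parameter landscape has shallow valleys when the traces are noisy.

**Synthetic traces.**  The original calibration data are normalized
two-photon fluorescence time courses (protein/volume ratios) digitized
from a published figure; this package does not digitize figures.  Instead
`generate_synthetic_series()` emulates their structure: baseline 1, a
one-minute stimulus-driven rise, exponential relaxation, and i.i.d.
additive Gaussian noise (default σ = 0.05, about the scatter of sparse
imaging time courses; 13 samples spans a typical acquisition).  What
passing the recovery tests shows is that the fitting machinery identifies
the generating kinetics from data *of that form*; it cannot certify the
biological parameters themselves, since real traces carry correlated
noise, bleaching trends, and bound-vs-free protein ambiguity that the
generator deliberately omits.

## Numerics

* **Lattice and signed distance.**  The lattice is fixed (spacing
  $\Delta_x$, default 0.0315 µm) and must contain the mesh with margin.
  Nearest-element queries are exact: a uniform face-bucket grid with an
  expanding-ring search returns results bitwise identical to exhaustive
  search (asserted in tests), with ties broken toward the lowest face
  index for reproducibility.  The inside/outside sign comes from the
  angle-weighted pseudonormal at the exact closest feature — provably
  correct on watertight meshes — with a generalized winding-number
  fallback for glancing queries ($|\mathbf{w}\cdot\mathbf{n}| <
  10^{-9}|\mathbf{w}||\mathbf{n}|$); the winding number also serves as the
  sign oracle in the tests.  $\mathbf{d}$ is computed analytically from
  the closest point (unit norm by construction), never by differencing
  $d_s$; only divergences are differenced.
* **Advection.**  First-order upwind differences for all transport terms
  ($-\mathbf{v}\cdot\nabla B$, the $\mathbf{f}_u$ drift, bulk flow),
  central differences for $\nabla\cdot\mathbf{d}$ and
  $\nabla\cdot\mathbf{f}_u$, one-sided at the domain boundary.  Upwinding
  trades accuracy for stability against the nonsmooth direction field;
  the advection test quantifies the numerical diffusion and checks mass
  conservation to 1%.
* **Time stepping.**  Species are advanced over each global step
  $\Delta_t$ (default 0.01 s) by adaptive Dormand–Prince 4(5) sub-stepping
  (`deSolve`), after an advective CFL guard.  Reaction terms evaluate on
  values clamped at zero because adaptive sub-stages may transiently
  undershoot ($C^{3.5}$ is undefined for negative $C$); after each global
  step negatives are clipped to zero with the clipped mass logged, species
  are zeroed below the absorbing boundary and at points far outside the
  membrane ($d_s > 3/\beta$, where the potential has saturated).  The
  absorbing boundary sits at z = 0.3 µm (the neck base): the proteins'
  stable arrangement in the neck is outside this model's scope, and the
  location is configurable because it is genuinely underdetermined.
* **Forces as exact gradients.**  Both forces are implemented as exact
  gradients of their *discrete* energies.  The bending energy uses the
  cotangent Laplacian with barycentric dual areas,
  $E = \tfrac{\kappa}{2}\sum_v |\mathbf{K}_v|^2 / A_v$, and its gradient is
  hand-derived reverse-mode through the cotangents and areas.  The actin
  energy is the lattice sum $E_B = \sum_{\mathbf{r}\in\Omega} \psi\,B\,
  \Delta_x^3$, differentiated through the closest-element map:
  each interior point contributes
  $\Delta_x^3\,\tfrac{\alpha\beta}{2}\mathrm{sech}^2(\beta d_s)\,B$ along
  the outward direction, distributed to its closest face's vertices by
  barycentric weights (the envelope theorem kills the tangential variation
  of the closest point).  Gradient exactness is what lets central
  finite-difference oracles gate both assemblies at $10^{-3}$ relative.
* **Membrane update and remeshing.**  Forward Euler at the global step
  (the overdamped limit makes this a quasi-static update), with a
  step-size guard on per-vertex displacement and fixed dendrite-base
  vertices pinned.  Every 0.5 s of simulated time the membrane is
  remeshed by incremental isotropic remeshing (split > 4/3·target,
  collapse < 4/5·target under the link condition, valence-improving
  flips, tangential relaxation restricted to neighborhoods that actually
  changed, projection back onto the pre-remesh surface).  Fixed vertices
  are bitwise preserved; volume changes stay well under 1%.  The tracked
  protrusion vertex is rebound to the nearest vertex after each remesh.
  The distance field is refreshed whenever accumulated membrane
  displacement exceeds $\Delta_x/8$ (and always after remeshing), which
  bounds the staleness of the closest-element map by a fraction of a cell.
* **Initial shape.**  A surface of revolution — spheroid head (radius
  0.25 µm centred at z = 0.85 µm) on a cylindrical neck (radius 0.1 µm)
  on a base disc — remeshed isotropically, then relaxed under bending
  forces alone.  The relaxation is a gradient flow with automatic step
  halving whenever a trial step would raise the energy, which guarantees
  the monotone-descent property the tests check.  The head/neck
  dimensions are not printed in the source material; these defaults are
  chosen to be consistent with the measurement heights used for the neck
  (z ≈ 0.63 µm) and head (z = 0.84 µm) radii and are configurable.

## Parameters

| symbol | meaning | units | default |
|---|---|---|---|
| $k_\beta, k_A, k_C$ | decay/efflux rates | 1/s | 0.0081, 0.0013, 0.0006 |
| $I_\beta, I_A, I_C$ | basal influxes | µM/s | 24.4284, 0.0255, 0.0237 |
| $I_{S,\beta}, I_{S,A}, I_{S,C}$ | stimulus influxes | µM/s | 25.6684, 0.0293, 0.4384 |
| $k_{\mathrm{nuc}}$ | nucleation rate | 1/(µM·s) | 0.0153 |
| $k_{\mathrm{sev}}, k_n, n$ | severing rate, Hill constant, coefficient | 1/s, µM$^n$, – | 0.012, 0.6, 3.5 |
| $\Psi_0, \Psi_1$ | count/concentration conversions | see text | 3.6, 0.02 |
| $\nu, \xi, \eta$ | polymerization speed, flow restriction, filament mobility | µm/s, –, µm/(s·pN) | $10^{-5}$, 0.1, $10^{-10}$ |
| $\alpha, \beta$ | potential amplitude, steepness | pN, – | $3\times10^4$, 40 |
| $\kappa, \omega$ | bending modulus, drag | pN·µm, s·pN/µm | 0.18, $10^5$ |
| $\Delta_t, \Delta_x, \Delta_s$ | time step, lattice spacing, mesh edge | s, µm, µm | 0.01, 0.0315, 0.05 |

One scale-factor discrepancy is worth flagging: the printed derivation of
$\Psi_1$ (12 branches ÷ 602.214 molecules µm⁻³ µM⁻¹) gives 0.0199, and
the parameter table lists 0.02, but the accompanying text says
"≈ 0.2".  The derivation supports 0.02, which is what this package uses.

## Scenarios and presets

`scenario_catalog()` enumerates the experiment set: control; knockouts of
each stimulus influx; 50% enhancement of the Arp2/3+cofilin stimulus; a
±25% bending-modulus sweep; clutch/ECM perturbations — filament mobility
η×0.6, polymerization speed ν×1.4, drag ω×0.6, and combinations — applied
*during the stimulus window only* (they model stimulus-gated clutch
engagement and protease activity); and a repeated-stimuli protocol (three
one-minute windows separated by one-minute rests).

A practical point about equilibration: the pre-stimulus baseline creeps
toward mechanical equilibrium on a timescale set by the depletion of
barbed ends near the membrane (rate of order
$\eta\,\alpha\beta^2 \approx 5\times10^{-3}$ per second, i.e. minutes).
Comparisons *between* scenarios share this baseline drift and are
meaningful after the standard coupled-relaxation phase, but an absolute
"nothing happens without a stimulus" check requires a long relaxation
(about 12 simulated minutes at the reduced preset) before the window.
The lattice must also contain the grown spine: `margin_cells` sets the
headroom around the initial shape, and protocols with large cumulative
growth (the repeated-stimuli run) need a larger margin or a slightly
coarser lattice.

Two resolution presets exist.  `paper` is the full resolution
($\Delta_t = 0.01$ s, $\Delta_x = 0.0315$ µm, edge 0.05 µm, 1 min fixed
membrane + 3 min coupled equilibration + stimulus + 4 min post).
`reduced` ($\Delta_t = 0.05$ s, $\Delta_x = 0.06$ µm, edge 0.08 µm, with a
compressed 20 s + 40 s + 60 s + 60 s schedule) is the package's own
scaled-down study condition: it preserves every mechanism and the
qualitative orderings between scenarios while keeping a full run in the
minutes range, and it is the size at which the test suite and the
acceptance script exercise the scenarios.  Quantitative percent changes at
reduced resolution are larger than at full resolution (coarser lattice
cells concentrate the influx and the equilibration is shorter); the
orderings — actin-influx knockout suppresses growth, Arp2/3/cofilin
knockouts barely matter, reduced drag enhances growth, repeated stimuli
show diminishing gains — are the reproducible content.

## Known limitations

* Single-phase dynamic actin only: no stable pool, no neck actin rings,
  no filament length or orientation (barbed ends are a density).
* No membrane tension, osmotic pressure, self-intersection handling, or
  explicit adhesion dynamics; perisynaptic mechanics enter only through
  parameter perturbations.
* Protein transport through the neck from the dendrite is not modeled;
  the stimulus appears directly in the head.
* First-order upwinding introduces numerical diffusion of order
  $\nu\Delta_x$; at the default (tiny) transport speeds this is
  negligible, but steep-gradient regimes would need a higher-order
  scheme.
* The experimental spine shrinks again after the transient; this model
  settles to a larger size instead, as its mechanism set omits the
  processes responsible for the late shrinkage.
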