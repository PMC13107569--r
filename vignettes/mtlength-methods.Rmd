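---
title: "Modelling microtubule length regulation by motors at both ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microtubule length regulation by motors at both ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlength)
```

## The model

Non-centrosomal microtubules have two free, biophysically distinct ends.
`mtlength` models a single such filament on a one-dimensional axis (the
natural geometry for neurites), occupied by two depolymerizing motor
species: a slow, processive plus-end-directed motor (kinesin-8 type,
speed $v_+$, weak on-lattice diffusivity $D_+$) and a minus-end
depolymerase that reaches the tips by fast one-dimensional diffusion
along the lattice rather than directed stepping (kinesin-13 type,
$v_- = 0$, large $D_-$). Each species exchanges between a bound, moving
state ($p$ for the plus species, $m$ for the minus species) and an
unbound cytoplasmic state ($c$, $f$) with first-order kinetics
$k_\mathrm{on}, k_\mathrm{off}$; unbound motors diffuse with the common
cytoplasmic diffusivity $D$. These advection–diffusion–reaction
equations are the mean-field limit of a stochastic switching-particle
description; motor–motor exclusion is deliberately not modelled.

Densities are nondimensional, normalized so that the reservoir value
imposed at the boundaries is 1; the motor-driven shrinkage coefficients
$\gamma_\pm$ therefore carry units of µm/s per unit normalized density.
At the minus end the model imposes unit reservoirs of $p$, $c$ and $f$
and zero gradient of $m$; at the plus end, unit reservoirs of $c$, $m$,
$f$ and zero gradient of $p$. The zero-gradient conditions express that
bound motors exit the domain ballistically — the Fickian part of their
flux vanishes where they walk off the tip they depolymerize.

The tips obey

$$\frac{dL_+}{dt} = \alpha_+ - \beta_+ L - \gamma_+\, p(L_+), \qquad
  \frac{dL_-}{dt} = -\alpha_- + \beta_- L + \gamma_-\, m(L_-),$$

so the filament length $L = L_+ - L_-$ couples back to the motor fields
through the bound densities at the tips. The $\beta$ terms fold
non-motor length-dependent destabilization (e.g. ragged protofilament
ends; discrete catastrophe/rescue switching is not resolved) into an
effective rate.

## Parameters

Defaults (`default_params()`) come from published in vitro motor
measurements and in vivo tip-tracking in larval sensory neurons:

| parameter | plus motor | minus motor | units | note |
|---|---|---|---|---|
| $v$ | 0.05 | 0 | µm/s | kinesin-8 is slow/processive; kinesin-13 diffusive |
| $D_\mathrm{on}$ | 0.01 | 0.38 | µm²/s | on-lattice diffusion |
| $D$ | 4 | 4 | µm²/s | cytoplasmic |
| $k_\mathrm{on}$ | 1 | 1 | 1/s | baseline (measured rates are per motor concentration, which the model does not track) |
| $k_\mathrm{off}$ | 0.25 | 1.2 | 1/s | the minus motor's published range is 1.2–3 s⁻¹; the default takes the lower bound (longest-lived on the lattice) and is configurable |
| $\alpha_\pm$ | 0.15 | 0.02 | µm/s | maximal growth speeds, 9 and 1.125 µm/min, converted with `alpha_from_max_growth()`; the minus value is conventionally rounded from 0.01875 |
| $\beta_\pm$ | 0.05 | 0.0006 | 1/s | see below |
| $\gamma_\pm$ | 0.01 | 0.01 | µm/s per unit density | varied by the scenarios |

`beta_from_avg_growth()` derives $\beta$ from an average growth speed
via $dL/dt = \alpha - \beta L$ at the characteristic length
$\bar L = 10$ µm and returns the exact arithmetic: 0.75 µm/min at the
minus end gives 0.000625 s⁻¹ (conventionally rounded to 0.0006), and
6 µm/min at the plus end gives 0.005 s⁻¹. The scenario default for
$\beta_+$ is nevertheless **0.05 s⁻¹**, the value the baseline
disassembly regime was originally demonstrated with; the derivation
function and the scenario default are kept deliberately separate so the
factor-of-ten tension between them stays visible rather than being
silently resolved either way.

`validate_params()` enforces sign/finiteness invariants and warns when
binding kinetics are not fast compared with the transport rates $v/L$
and $D/L^2$, i.e. when the fast-switching reduction below is not
trustworthy.

## Reductions

**Fast switching.** When $k_\mathrm{on}, k_\mathrm{off}$ dominate
transport, each species' bound/unbound split relaxes to its duty ratio
$\kappa = k_\mathrm{on}/(k_\mathrm{on}+k_\mathrm{off})$ and the total
density obeys one effective equation with
$\mathcal V = \kappa v$ and
$\mathcal D = \kappa D_\mathrm{on} + (1-\kappa) D$
(`effective_parameters()`; baseline: $\mathcal V_+ = 0.04$ µm/s,
$\mathcal D_+ = 0.808$ µm²/s, $\mathcal D_- = 2.355$ µm²/s). The
two-field system (`simulate_reduced_pde()`) carries a Dirichlet
reservoir for $q$ at the minus end, the flux condition
$\mathcal V_+ q - \mathcal D_+ q_x = 1$ at the plus end, a Robin
condition $h + h_x = 1$ at the minus end and a Dirichlet reservoir for
$h$ at the plus end, all exactly as the reduction states them.

**Adiabatic limit.** Assuming the fields equilibrate faster than the
tips move, the steady profiles
$q(x) = (1 + 1/\mathcal V_+)e^{(\mathcal V_+/\mathcal D_+)(x-L_-)} - 1/\mathcal V_+$
and $h \equiv 1$ close the tip equations into the scalar flow
`adiabatic_length_flow()`. Writing it as a decreasing gain $f(L)$ minus
an increasing loss $g(L)$ shows a unique positive equilibrium $L^\dagger$
exists iff $\alpha_+ + \alpha_- > \gamma_+ + \gamma_-$
(`equilibrium_length()`); $\beta_\pm$ move the equilibrium but cannot
create or destroy it. A generic equilibrium treadmills; truly fixed
ends require the two tip nullclines — parallel unit-slope lines — to
coincide, a condition evaluated in closed form through the principal
branch of the Lambert-W function (`fixed_end_residual()`; the argument
is positive for positive parameters, so the principal branch is the
real one).

### Known internal inconsistencies of the reduced tier

Two boundary-condition subtleties of the stated reduction deserve
attention, because the package reproduces them *as stated* rather than
repairing them:

1. **Plus-species flux sign.** The closed-form $q(x)$ above satisfies
   $\mathcal V_+ q(L_+) - \mathcal D_+ q'(L_+) = -1$, not the $+1$ the
   reduced PDE imposes. `steady_profile_robin()` solves the steady
   problem for arbitrary flux data $s$ (the $s=-1$ solution is the
   canonical antenna profile; the $s=+1$ solution decreases and turns
   negative for $\mathcal V_+ < 1$). Consequently
   `simulate_reduced_pde()` relaxes $q$ to the $+1$-consistent profile,
   while the adiabatic flow uses the canonical printed profile — and
   the two tiers disagree quantitatively (e.g. adiabatic
   $L^\dagger = 5.6$ µm vs the full model's 10 µm treadmill). The reduced
   boundary data also normalize the *total* reservoir density to 1
   whereas the full model pins each component to 1 (total 2), so
   full-model totals do not converge to the reduced fields near the
   boundaries even at fast switching; the test suite measures this gap
   rather than asserting it away.
2. **Minus-species Robin sign.** At a left boundary the condition
   $h + h_x = 1$ carries a negative coefficient on the outward normal
   derivative, so the continuum problem it closes is *anti*-dissipative:
   $h \equiv 1$ is an exact fixed point but perturbations grow at rate
   $\mathcal D_- \mu^2$ with $\tanh(\mu L) = \mu$ (≈2.4 s⁻¹ at
   $L = 10$ µm), which the discrete solver reproduces. Steady-state
   checks therefore start from the uniform reservoir state, which the
   scheme preserves exactly; the gradient term is taken with an
   implicit 1 µm length scale, the only reading available. ($h\equiv1$
   satisfies the condition under any length scale.)

## Numerical methods

* **Moving domain.** The physical domain is mapped to the fixed
  reference interval $\xi \in [0,1]$ via $x = L_- + \xi L$ (an
  arbitrary Lagrangian–Eulerian transform). Each field gains a
  mesh-motion advection term with node velocity
  $\dot x(\xi) = \dot L_- + \xi(\dot L_+ - \dot L_-)$, folded into the
  physical advection velocity before discretization.
* **Space.** Second-order central differences for diffusion;
  first-order upwinding on the *total* (physical minus mesh) advection
  velocity, chosen for positivity and robustness over formal order.
  Default 100 cells; doubling to 200 moves the asymptotic lengths of
  all four built-in scenarios by well under 1% of $\bar L$ (the
  refinement test), so 100 is used for routine work and by the
  acceptance script. Dirichlet nodes are pinned exactly; zero-gradient
  and Robin nodes are closed with one-sided first-order stencils, which
  makes the boundary the accuracy bottleneck (O(dx) there).
* **Time.** `deSolve::lsodar` integrates the concatenated state (all
  field nodes plus both tips) with `rtol = 1e-6`, `atol = 1e-9` and
  event roots at the termination cutoffs: `L_min = 0.1` µm
  ("disassembled" — the transformed equations are singular as
  $L \to 0$) and `L_max = 100` µm ("runaway").
* **Initial data.** All densities start at the reservoir value 1
  (`uniform-one`), which minimizes boundary-layer transients and is a
  natural choice given that the underlying study does not pin initial
  conditions down; `zero-interior` is available for relaxation
  experiments.
* **Root finding.** The adiabatic equilibrium is bracketed (upper bound
  expanded geometrically until the flow is negative), solved with
  `uniroot`, and polished by Newton steps with the analytic flow
  derivative to drive $|dL/dt|$ below $10^{-10}$. This replaces any
  need for continuation methods: the flow is a monotone-decreasing
  scalar function.
* **Lambert-W.** `lambert_w0()` is implemented in the package (damped
  Halley for $x \le 2$, Newton on the logarithmic form
  $w + \log w = \log x$ otherwise, bounded iterations, overflow-safe up
  to the largest double). An off-the-shelf implementation was found to
  enter a non-terminating iteration on specific large arguments that
  the nullcline condition actually produces; it is retained in the test
  suite as an independent cross-check on benign arguments only.

## Scenarios and what they show

`builtin_scenario()` ships four parameter regimes, all from
$L_0 = \bar L = 10$ µm with baseline kinetics:

* **disassembly** ($\beta_+ = 0.05$): rapid, monotone, initially linear
  shrinkage dominated by the plus end (≈−0.36 µm/s at the start), with
  slow sustained growth at the minus end. As $L$ falls the $\beta_+ L$
  term weakens and the run settles toward a short (≈2.3 µm)
  slowly-translating state rather than reaching the cutoff: with the
  stated boundary reservoirs, the tip densities are capped by their
  binding equilibria ($p(L_+) \lesssim k_\mathrm{on}/k_\mathrm{off}
  \cdot c \approx 4$), so the loss terms cannot exceed
  $\gamma_+ p + \gamma_- m \approx 0.05$ µm/s and intrinsic growth wins
  at small $L$. 300 s horizon.
* **treadmilling** ($\beta_+ = 0.0116$): length pinned at ≈9.98 µm for
  the whole 600 s horizon (10 minutes, showing the state is sustained)
  while both tips translate at ≈0.0057 µm/s — the central prediction
  that length homeostasis is maintained *dynamically*.
* **fixed-ends** ($\beta_+ = 0.011$, $\beta_- = 0.00117$): both tip
  speeds fall below $4\times10^{-5}$ µm/s and the length holds at
  ≈10.0005 µm — the constrained regime in which both nullclines
  coincide, reachable only by tuning both $\beta$s. 300 s horizon.
* **patronin-rnai** ($\gamma_- = 0.05$): loss of minus-end protection
  modelled as amplified motor-driven minus-end depolymerization. The
  filament shrinks by ≈27% and then — for the same tip-density-cap
  reason as above — settles into a fast-translating steady state at
  ≈7.2 µm rather than disassembling completely. The adiabatic existence
  condition agrees ($0.17 > 0.06$), so within this model full
  disassembly under this perturbation would require either stronger
  $\gamma_-$, a larger bound-motor reservoir, or kinetics outside the
  stated ranges. The classification test records this honestly as a
  non-disassembling outcome.

`classify_trajectory()` labels runs from trailing-window diagnostics
(defaults: window 20% of the run, length-rate and tip-speed tolerances
both $10^{-3}$ µm/s — chosen so that the treadmilling tips, an order of
magnitude above, and the fixed-end tips, an order of magnitude below,
are separated robustly; classification is invariant to 2× subsampling).
`parameter_sweep()` varies one parameter at a time, as the
one-dimensional structure of the comparative statics suggests
($L^\dagger$ increases with $\alpha_\pm$, decreases with $\beta_\pm$,
$\gamma_\pm$ — verified by perturbation tests).

## Problem sizes

Routine and test runs use 100 reference cells (200 for the refinement
checks, 32–64 where the length dynamics decouple from the fields);
scenario horizons are 300 s (600 s for treadmilling, where persistence
is the point). At these sizes a full-model scenario integrates in a few
seconds on one core and the entire test suite in under two minutes.

## Limitations

Beyond the reduced-tier inconsistencies above: the model is mean-field
(no motor–motor exclusion, no stochastic tip switching — catastrophe is
an effective rate, not a state), single-filament (no ensembles, no
shared motor pools), and one-dimensional. Passing the synthetic-scenario
suite shows the implementation is faithful to the stated equations and
internally convergent; it does not validate the biological parameter
choices, and regimes that depend on boundary-layer details (anything
within ~$\mathcal D/\mathcal V$ of a tip) inherit the first-order
accuracy of the boundary stencils.
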