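---
title: "A free-boundary multiphase model of early plaque growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A free-boundary multiphase model of early plaque growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(plaquesim)
```

## The model

plaquesim simulates the earliest stage of atherosclerosis: the growth of a
fatty streak in the intima, the artery-wall layer between the endothelium and
the media. The intima is modelled as a one-dimensional interval $[0, R(t)]$
— a radial transect through the wall, with $x = 0$ at the endothelium and the
moving boundary $x = R(t)$ at the elastic lamina separating intima from
media. Three phases fill the tissue: live macrophage foam cells $f$, modified
LDL (modLDL) $l$, and dead cellular material $c$, measured as fractions of a
close-packed reference density so that the *no-voids* constraint

$$f + l + c = 1$$

holds everywhere. Each phase obeys a continuity equation

$$\partial_t u = -\partial_x (J_u + v\,u) + s_u, \qquad u \in \{f, l, c\},$$

with interphase fluxes

$$J_f = -D_f \partial_x f + \chi_l f\, \partial_x l + \chi_c f\, \partial_x c,
\qquad J_l = -D_l \partial_x l, \qquad J_c = -D_c \partial_x c,$$

(random motility plus chemotaxis of foam cells towards modLDL and towards the
find-me signals of dying cells; Fickian diffusion for the passive phases) and
mass-exchange kinetics

$$s_f = \mu_p f l + \mu_e f c - \mu_a f, \qquad
  s_l = -\mu_p f l, \qquad
  s_c = \mu_a f - \mu_e f c.$$

Phagocytosis ($\mu_p$) converts modLDL into foam-cell volume, efferocytosis
($\mu_e$) recycles dead material into live cells, and death ($\mu_a$, with
apoptosis and necrosis lumped together) converts live cells into dead
material. The terms cancel pairwise, so the kinetics conserve mass locally —
the property that makes the mixture velocity closure possible.

Because the phases fill space, summing the three continuity equations forces
the total material flux to be divergence-free, which integrates (using the
endothelial boundary conditions) to a *closed-form* common advection velocity

$$v = \sigma_f l|_{0} + \sigma_l + D_f \partial_x f
      - \chi_l f \partial_x l - \chi_c f \partial_x c
      + D_l \partial_x l + D_c \partial_x c,$$

and the boundary moves at the net rate of material exchange,

$$\frac{dR}{dt} = \sigma_f\, l|_{x=0} + \sigma_l - \sigma_e\, f|_{x=R}.$$

At the endothelium, LDL deposits at constant rate $\sigma_l$ (entering as
modLDL, since chemical modification is fast on growth timescales) and
monocytes are recruited in proportion to endothelial modLDL ($\sigma_f
l|_0$), entering as foam cells; dead material has zero influx. At the medial
boundary, foam cells emigrate into the lymphatics with egress velocity
$\sigma_e$ (a flux boundary condition, not a sink term — mass leaves through
the boundary, conservatively); the passive phases satisfy no-flux conditions
relative to the moving boundary. The initial state is a pristine intima of
unit width populated by resident macrophages: $f = 1$, $l = c = 0$, $R = 1$.

### Parameters

All quantities are nondimensional: lengths in macrophage diameters
(16 µm), times in weeks (the timescale of murine plaque experiments),
densities relative to close packing. `nondimensionalise()` converts
dimensional estimates using exactly these rescalings. Defaults in
`plaque_params()`:

| parameter | meaning | default |
|---|---|---|
| $D_f$ | foam-cell random motility | 20 |
| $D_l$ | modLDL diffusivity | 200 |
| $D_c$ | dead-material diffusivity | 10 |
| $\chi_l$ | chemotaxis towards modLDL | 1000 |
| $\chi_c$ | chemotaxis towards dead material | 500 |
| $\mu_a$ | foam-cell death rate | 40 (variable, 10–100) |
| $\mu_e$ | efferocytosis rate | 60 (variable, 10–200) |
| $\mu_p$ | phagocytosis rate | 300 |
| $\sigma_f$ | monocyte recruitment per unit modLDL | 100 |
| $\sigma_l$ | LDL deposition rate | 10 |
| $\sigma_e$ | foam-cell egress velocity | 0 (variable, 0–100) |

The three *variable* parameters are the biological dials of the model: the
death/efferocytosis pair controls deep-plaque composition, and the egress
velocity controls whether the plaque can stabilise. Values outside the
quoted ranges are accepted with a warning, since the fixed parameters are
order-of-magnitude estimates and the model loses calibration far outside
them.

## The deep-plaque characteristic ODE

Away from the boundaries, transport is dominated by bulk advection: all
phases move with nearly the common velocity $v$, and modLDL has been
consumed. Along an advection characteristic the foam-cell fraction $F$
(with $C = 1 - F$) then obeys the logistic-type equation

$$\frac{dF}{dt} = \mu_e F \left(1 - \frac{\mu_a}{\mu_e} - F\right),$$

with steady states $F^* = 0$ and $F^* = 1 - \mu_a/\mu_e$ and linearisation
eigenvalues $\mu_e - \mu_a$ and $\mu_a - \mu_e$ respectively. The two
branches exchange stability in a transcritical bifurcation at $\mu_a =
\mu_e$: efficient efferocytosis ($\mu_e > \mu_a$) sustains a coexistence
of live and dead material in the deep plaque, while defective efferocytosis
drives complete foam-cell extinction there — and with it, the loss of the
emigration route, since only live cells leave. `steady_states()`,
`stability_eigenvalues()` and `bifurcation_table()` expose this analysis;
`solve_characteristic()` integrates the ODE numerically and
`logistic_characteristic()` is its closed-form solution, kept as an
independent oracle (the test suite checks their agreement at $10^{-8}$
relative tolerance over random parameter draws, using near-zero absolute
tolerance so that even deeply decayed trajectories are compared in relative
terms). At $\mu_e = 0$ the dynamics degenerate to pure exponential decay,
and at $\mu_a = \mu_e$ the solver reports the single degenerate state with
zero eigenvalue rather than two coincident ones.

## Numerical method

The moving domain is mapped onto $y = x / R(t) \in [0, 1]$, turning the
system into parabolic equations with an extra mesh-advection term coupled to
the ODE for $R$:

$$\partial_\tau u
  = \frac{1}{R}\,\partial_y\!\big(R' y\, u - j_u\big) - \frac{R'}{R} u + s_u,
  \qquad j_u = J_u + v u .$$

Writing the mesh term conservatively (inside the divergence) is deliberate:
summed over any set of grid cells, the discrete fluxes telescope and the
global mass budget matches the boundary fluxes exactly.

Space is discretised in finite-volume flux form on a uniform $y$-grid of
`n_cells` intervals, with half-cells at the two boundary nodes. Interior
face fluxes use compact two-point gradients and arithmetic-mean face values
(second-order central differencing). Two discrete choices matter:

* **Discrete velocity closure.** The face mixture velocity is evaluated
  from the *same* face gradients as the phase fluxes, mirroring at the
  discrete level the derivation of $v$ from the no-voids constraint. As a
  consequence $j_f + j_l + j_c = \sigma_f l|_0 + \sigma_l$ holds exactly at
  every face wherever $f + l + c = 1$, and the constraint is an invariant
  of the semi-discrete system: its residual reflects time-integration error
  (about $10^{-6}$ at the default tolerances), not spatial truncation.
  Spatial accuracy is therefore assessed on observables — the test suite
  verifies a Richardson ratio near 4 for $R(1)$ across grid doublings, the
  signature of a second-order scheme.
* **Boundary closure.** The flux boundary conditions are imposed exactly as
  the boundary-face fluxes of the two half-cells: $(\sigma_f l|_0,\,
  \sigma_l,\, 0)$ at the endothelium and, relative to the moving boundary,
  $(\sigma_e f|_R,\, 0,\, 0)$ at the media. The value $l|_0$ used in $v$,
  in $dR/dt$ and in the monocyte influx is the endothelial node value — one
  consistent definition everywhere.

Phase fractions are never clipped: negativity would break the conservation
identities, so it is only monitored. `simulate_plaque()` warns when
$\max|f+l+c-1|$ or the worst undershoot exceeds its tolerance and fails hard
beyond ten times it, treating a large breach as a model-inconsistency signal
rather than something to repair silently.

The semi-discrete system (about 600 unknowns at the default `n_cells = 200`)
is stiff — chemotactic coefficients up to $\chi_l/D_f = 50$ steepen the
endothelial boundary layer — and is advanced with a BDF integrator
(`deSolve::lsode`, full internally-generated Jacobian) at `rtol = 1e-8`,
`atol = 1e-10`.

An upwind option replaces the arithmetic-mean advected face values with
donor-cell values selected by the sign of the common mesh-relative advection
velocity $w = v - R'y$. Using one donor selection for *all* phases keeps the
no-voids constraint exact for the upwind scheme too (per-phase upwind
velocities would break the flux cancellation); chemotactic drift remains in
central flux form. Upwinding is first-order and slightly diffusive — the
test suite checks that bulk observables agree with the central scheme at the
percent level — and is provided for robustness on coarse grids, where
central advection of the bead pulse can produce small dispersive
undershoots.

### Numerical choices and degenerate cases

* `tol_voids = 1e-4`, warn threshold for the no-voids residual; typical
  values are orders of magnitude smaller.
* `tol_neg = 1e-4`: sized to the dispersive undershoot of central transport
  of the bead tagging pulse at the default grid (a few $10^{-5}$, about
  0.025% of the pulse amplitude). The phase fractions themselves remain
  non-negative to much tighter accuracy; beads are the only near-pure
  advection problem in the system because their "diffusion" is inherited
  from the carrier only where the carrier has gradients.
* Bead flux regularisation: $J_{q_u} = (q_u/u) J_u$ is set to zero where the
  carrier fraction is below $10^{-10}$ — the physical $0/0$ limit of an
  absent carrier (dead material is absent everywhere at $t = 0$).
* $R \ge 1$ is *not* enforced. For egress velocities above the deposition
  rate the initial state ($f|_R = 1$) gives $dR/dt = \sigma_l - \sigma_e <
  0$, and strongly-stabilised plaques settle below their initial width;
  this is the correct behaviour of the growth law, and only $R > 0$ is
  required.
* The model is fully deterministic; `solver_config()` carries an inert
  `seed` field purely so configurations round-trip.

### The initial deposition transient

From a pristine intima the endothelial modLDL level grows like $\sqrt{t}$
(constant-flux deposition into a diffusing layer), so $dR/dt$ has a
square-root singularity at $t = 0$, and in emigration scenarios it also
swings from negative (egress of the initial resident cells) to positive
within $t \approx 0.01$. Trajectory audits that compare finite differences
of $R(t)$ against the growth law therefore need log-refined early snapshot
times; with uniform snapshots the first interval merely averages over the
transient. `conservation_report()` compares each snapshot interval's slope
with the trapezoidal mean of the law, normalised by the trajectory's
growth-rate scale (the pointwise rate crosses zero in stabilising runs).

## Bead tagging

To track macrophage cohorts in a continuum model, two volume-less tracer
densities ride the phases: $q_f$ on live foam cells and $q_c$ on dead
material. They move with their carrier's velocity ($J_{q_u} = (q_u/u) J_u$
plus bulk advection), are handed from live to dead at the death rate and
recovered by efferocytosis at rate $\mu_e f$, and leave only with emigrating
foam cells. The coupling is strictly one-way; the test suite verifies that
phase trajectories with and without beads are identical, and that tracers
initialised proportional to their carriers stay proportional (with a closed
endothelium, where phagocytosis — which creates foam-cell volume but not
beads — is inactive).

Tagged monocytes enter as a unit-peak Gaussian endothelial influx of width
$0.035$ (about six hours) centred on each dose time; multiple doses add
linearly. The total bead quantity $Q(t) = \int_0^R (q_f + q_c)\,dx$ rises to
at most the time-integrated dose ($0.035\sqrt{2\pi} \approx 0.0877$ per
dose) and then falls as tagged cells emigrate — or fails to fall when
efferocytosis is defective and the tagged material is locked in dead
cells. The *circulation time* summarises a cohort's residence: the full
width at half maximum of $Q(t)$, with linear interpolation between stored
samples at the two crossings (`circulation_time()`; a series still at half
maximum at the end of the record is flagged as right-censored and returns
the observable lower bound). Resolving the dose window requires snapshot
spacing well under $0.035$; the default output grid (100 snapshots per unit
time) gives three to four samples per dose width, and the FWHM of $Q$ itself
is an order of magnitude wider.

## A worked example

```{r base-run, eval = FALSE}
sim <- simulate_plaque(plaque_params(mu_a = 40, mu_e = 80),
                       solver_config(n_cells = 200, t_end = 1))
glance(sim)
autoplot(sim)
```

With $\mu_e/\mu_a = 2$ the deep plaque settles towards the ODE coexistence
state $1 - \mu_a/\mu_e = 0.5$: the test suite checks
`medial_density(sim, 1)` against $0.5$ within $\pm 0.05$, and the
conservation audit bounds the no-voids residual by $10^{-4}$, the mass
residual $|\int (f+l+c)\,dx - R|$ by the same, and the growth-law mismatch
by 1% for every scenario preset.

## What the scenario presets emulate — and what they do not

The presets in `plaque_presets()` are the studied parameter regimes: the
baseline efferocytosis-dominant plaque, the four death/efferocytosis ×
emigration combinations, an ineffective-emigration and a stabilising
regime, and the two bead-tagging scenarios (efficient clearance, where
$Q(t)$ returns to zero, and defective efferocytosis, where it stays high).
They emulate the *structure* of early murine plaques under controlled
rates. They do not emulate: multi-dimensional geometry (a 1-D transect
cannot show lateral spreading or shoulder regions), heterogeneity in
macrophage phenotype or cholesterol load (one lumped foam-cell phase),
HDL-mediated efflux, or fluctuations — the model is a deterministic
continuum, so agreement in the tests shows the transport-kinetics scaffold
behaves correctly, not that parameter values are calibrated to any
particular animal.

## Problem sizes used by the checks

The test suite runs the presets at the default resolution (`n_cells = 200`,
the grid that resolves the endothelial boundary layer at second order),
grid-convergence comparisons at 100/200/400 cells, and the trend sweeps
(emigration, circulation times) at 100–200 cells with horizons $t \le 3$ —
sizes chosen so the whole suite exercises every regime of the model in a
few minutes on one core. Longer horizons change none of the qualitative
outcomes: stabilised plaques have already reached their steady width by
$t = 3$, and retained bead totals are flat.

## Known limitations

* One spatial dimension; the mixture-velocity closure is special to 1-D
  (higher dimensions would need a constitutive law such as Darcy flow).
* The kinetics are mass-action with constant coefficients; no saturation of
  efferocytic capacity, no cholesterol-dependent death.
* The emigration flux is linear in the medial foam-cell density, so
  stabilisation thresholds scale directly with $\sigma_e$.
* The bead tracer assumes beads never detach from cellular material and
  occupy no volume.
* Dimensional parameters are order-of-magnitude estimates; results should
  be read as regime maps in $(\mu_a, \mu_e, \sigma_e)$, not quantitative
  predictions.
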