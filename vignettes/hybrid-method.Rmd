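---
title: "The hybrid deterministic-stochastic method: models, discretization, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid deterministic-stochastic method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The class of models

hybridrd simulates spatial piecewise-deterministic Markov processes: systems
in which continuous concentration fields evolve deterministically by
reaction–diffusion PDEs between the jump events of a discrete stochastic
subsystem, while the two sides are coupled in both directions.  The
continuous ("U-type") variables are concentrations such as cytosolic calcium
or a ligand; the discrete ("Ξ-type") variables are individual particles —
channels, receptors, macromolecules — each carrying a position and one state
from a declared state set.  Couplings run both ways: particles act as point
sources or sinks of the fields (a channel releasing calcium at flux $J$ when
open), and the particles' transition rates may depend on the local field
value (a channel whose opening rate is $k_{on} U(\mathbf r,t)/U_0$, a
receptor activated at rate $k_3 S(\mathbf r,t)$ by the membrane density it
itself helps to build).

The canonical example wired into the package is the calcium-spark model:

$$\partial_t U = \nabla\!\cdot\!(D\nabla U) \;+\; J\sum_{i=1}^{N_{ch}}
\delta(\mathbf r-\mathbf r_i)\,\xi_i(t) \;-\; V_p\,(U-U_0),$$

with no-flux boundaries and two-state channels $\xi_i\in\{0,1\}$ switching
with rates $k_{on}$ (possibly field-dependent) and $k_{off}$.  The two other
built-in models are stochastically gated reversible binding (a ligand field
with Dirichlet boundary depleted locally by binding to immobile three-state
macromolecules) and spontaneous cell polarization (a cytosolic pool, a
membrane surface density, and two-state surface receptors with
state-dependent mobility and a positive feedback loop).

## One shared spatial discretization

Both subsystems live on one finite-volume partition.  A rectangular box is
divided into equal cells $\omega_j$ (lexicographic order, x fastest); a
closed membrane is a subdivided-icosahedron triangulation whose elements
play the same role.  Point particles are *binned*: the density of particles
of a species in state $s$ is, in cell $j$, the count inside $\omega_j$
divided by $|\omega_j|$.  This makes the stochastic source terms
well-defined on the PDE grid — an open channel contributes $J n_j/|\omega_j|$
to the concentration rate in its cell — and, conversely, a particle reads the
field of its own cell, piecewise-constant, with no interpolation.  Keeping
the two sides on the same grid means every reference comparison in the
validation battery shares the hybrid solver's spatial discretization, so
discrepancies measure the stochastic-deterministic coupling, not mesh
mismatch.

Cells are half-open, $[\mathrm{low},\mathrm{high})$ on every axis, with the
global upper boundary closed, so boundary-touching particles have exactly one
home.  Surface particles are stored as (triangle, barycentric coordinates),
so membership of the membrane is exact by construction rather than enforced
by projection tolerances.

## The fixed-time-step loop

One step of `hybrid_step()` executes, in order:

1. **Fields.** Each field takes a semi-implicit finite-volume step: the
   diffusion operator acts on the unknown at $t+\Delta t$, while reactions,
   membrane fluxes, and the binned particle sources are evaluated from the
   state at time $t$.  The linear system $(I-\Delta t\,L)U^{t+\Delta t}=U^t+
   \Delta t\,s(t)$ is solved by a cached sparse Cholesky factorization.
2. **Particles.** Each particle undergoes at most one transition, accepted
   when a uniform draw falls below the exact one-step probability
   $1-e^{-k_{tot}\Delta t}$ at rates frozen from time $t$; with several
   destinations, the same draw is partitioned proportionally to the rates.
   Mobile particles then take a Brownian step: the exact free-diffusion
   propagator (Gaussian, variance $2D\Delta t$ per axis) with specular
   reflection at walls, or a tangent-plane Gaussian step reprojected onto the
   membrane by walking the mesh.
3. **Rates.** Field-dependent transition rates are refreshed from the new
   fields at the new particle locations and cached for the next sweep.
4. **Densities.** Binned densities used by the couplings are re-derived from
   the updated particle arrays.

The ordering is part of the contract; `step_order = "particles_first"` swaps
phases 1 and 2, and the two orderings differ at $O(\Delta t)$ (this is
verified on the separable spark model, where common random numbers make the
channel paths identical so the field difference isolates the ordering
error).  The slight asynchrony between the phases is the method's
characteristic approximation; it can break local mass conservation in
strongly coupled binding problems, which stays small when $\Delta t$ is
small.  A hard runtime guard refuses any step in which some particle's
rate times $\Delta t$ reaches 0.5 — silently inaccurate sampling is treated
as an error, not a warning.

Reaction terms are explicit (evaluated at $t$) even when stiff; stiffness
mitigation is out of scope and the step-size constraint is documented
instead: $\Delta t \ll 1/\max(k)$ for all rates, with the guard as the
tripwire.  Negative concentrations produced by explicit sinks are *not*
clipped (clipping would silently break conservation); they are reported, and
any rate evaluation that reads a negative field value clamps that rate at
zero with a warning and an event count.

## Ensembles, random numbers, reproducibility

`run_ensemble()` propagates $n$ realizations either *collectively* — all
realizations in one vectorized state, fields as `ncell x n` matrices, one
factorized multi-right-hand-side solve per field per step — or as
*streams*, one realization at a time, each seeded `base_seed + id`.  The
two modes run identical step code.  Stream mode is the per-trajectory
reproducibility contract: a realization is bit-identical in isolation,
independent of ensemble layout or execution order.  Collective mode is the
throughput mode used for the large validation ensembles; it is reproducible
as a whole from `(base_seed, n)`.  This is a deliberate trade: a single
global RNG stream cannot serve per-realization streams and vectorized draws
at once.  Observables (spatial means, state counts, their ensemble mean and
variance) are computed online per recorded time; full per-realization
snapshots are stored only at requested times.

## Reference solvers

Validation never compares the engine against itself:

* **Separable closed form.** When channel rates are field-independent, the
  expectation of the spatial average has the closed form implemented in
  `analytic_mean_spark()` (mean open probability of a two-state chain driving
  a linear ODE; independent of $D$ because diffusion integrates to zero
  under no-flux boundaries).  The formula is itself cross-checked against an
  adaptive ODE integration in the tests.
* **Gibson–Bruck next-reaction method** (`gibson_bruck_simulate()`, C++): a
  statistically exact event-driven simulator for well-mixed mass-action
  networks, free of time-discretization error, with the indexed priority
  queue, dependency graph, and absolute-time reuse of unfired reaction
  times.  It is the reference for the fully coupled model in the
  fast-diffusion limit, where the spatial model must become well-mixed.
* **Direct Fokker–Planck solvers.**  For the nondimensional single-channel
  model ($\rho=(U-U_0)/U_0$, $\tau=tV_p$, $\alpha=k_{off}/V_p$,
  $\beta=k_{on}/k_{off}$, $a=J/(U_0V_p|\Omega|)$), `fp_fast_solve()`
  integrates the two-component hyperbolic system (drift $-\rho$ for the
  closed state, $a-\rho$ for the open state, exchange
  $R=\alpha(p_1-\beta(\rho+1)p_0)$).  `fp_functional_solve()` generalizes to
  finite diffusion on a coarse spatial grid of 2 or 3 nodes: each node
  contributes one advection coordinate with drift
  $d(\hat L\rho)_i-\rho_i+\xi\,(a/\Delta x)\delta_{i0}$, the point source
  discretized exactly as the engine bins it.  Both use donor-cell upwind
  transport with explicit Euler at CFL 0.5 — chosen for positivity and
  conservation over formal order — and conserve total probability to the
  tolerances asserted in the tests.  `richardson_extrapolate()` provides
  mesh-limit extrapolation for sequences of such solves.

Numerical defaults that had to be fixed somewhere: linear solves by sparse
Cholesky with an optional residual check at $10^{-10}$ relative; the
$\rho$-ranges of the Fokker–Planck grids are 1.2 times the all-open steady
state of the binned deterministic system, a bound the drift field cannot
leave; histogram comparisons use 20 equal bins with frequencies divided by
the bin width, and L2 differences are reported both absolutely and as a
percentage of the reference maximum.

## Surface diffusion

The Laplace–Beltrami operator is discretized element-centred: the flux
between adjacent triangles is $D\,\ell_e/d_e\,(S_k-S_j)$ with $\ell_e$ the
shared edge length and $d_e$ the centroid-to-centroid distance through the
edge midpoint.  Element-centred (rather than the vertex-centred cotangent
scheme) keeps the surface field in the same per-element form as the binned
surface particles and conserves mass exactly by antisymmetry.  On the
icosphere the decay rate of a degree-1 spherical harmonic converges to the
exact eigenvalue $2D/R^2$ under refinement (2.1% error at 320 elements,
0.4% at 1280 — the package's default resolution).

## Built-in models and their study conditions

* **Calcium sparks** (`build_spark_model()`): quasi-2D box
  $[0,10.1]\times[0,2.1]\times[0,0.5]\,\mu m^3$, $J=10$, $U_0=0.1\,\mu M$,
  $k_{off}=5/s$, $V_p=1/s$, $N_{ch}=24$; separable variant $k_{on}=1/s$,
  $D=1\,\mu m^2/s$, $\Delta t=2\,ms$, $T=5\,s$; coupled variant
  $k_{on}=0.1/s$ at $U=U_0$, $D=1000\,\mu m^2/s$, $\Delta t=0.2\,ms$.  The
  channel layout is a regular 12×2 grid — a fixture standing in for
  clustered arrangements; separable statistics are position-independent.
* **Gated binding** (`build_gated_model()`): $L_0=1\,\mu M\approx602\,
  \mu m^{-3}$, $r_c=(0.3/4\pi L_0)^{1/3}$, $\tau_D=r_c^2/D$,
  $a=b=1/\tau_D$, $\kappa_f=4\pi Dr_c$, $\kappa_r=\kappa_f L_0$; full scale
  $N=20000$ in $[0,10]^3$ at $h=0.2\,\mu m$, $\Delta t=10^{-5}\,s$.  The
  desk-scale study keeps the number density (20 per $\mu m^3$) on
  $[0,2.5]^3$ with $N=312$, $h=0.25\,\mu m$ (the coarsest mesh dividing the
  scaled box near the full-scale $0.2\,\mu m$), $n=200$ realizations,
  $T=110\,\tau_D$ (the horizon of the equilibrium estimator, which we
  average over the last $10\,\tau_D$ to reduce Monte-Carlo noise).
* **Polarization** (`build_polarity_model()`): sphere $R=4\,\mu m$,
  $U_0=1\,\mu M$, $D_S=D_\Gamma=0.1\,\mu m^2/s$, $k_1=0.01\,\mu M^{-1}s^{-1}$,
  $k_2=0.01/s$, $k_4=0.1/s$, pulse $k_0 e^{-t/\tau}$ with $k_0=10/s$,
  $\tau=1\,s$.  The benchmark unit quoted for $k_3$ ($\mu m^{-2}s^{-1}$) cannot make
  $k_3S$ a rate when $S$ is a surface density; here $k_3$ carries
  $\mu m^2 s^{-1}$ (value 0.01 at full scale), which is the reading that
  makes the feedback loop dimensionally consistent.  The cytosolic pool is
  treated as spatially uniform: with $D_U=10\,\mu m^2/s$ the mixing time
  $R^2/D_U\approx1.6\,s$ is far below the recruitment timescale
  $1/k_2=100\,s$, and the pool–membrane exchange is then exactly
  conservative by construction.  The scaled study uses $N_r=200$ receptors
  with $k_3=0.05$ so that the loop gain $\propto k_3N_r$ of the full model
  is preserved, $n=8$ realizations, $T=80\,s$, and counts clusters of
  active receptors by 1-$\mu m$ distance linkage (a diagnostic radius, not
  a model parameter).

Problem sizes above are the package's desk-scale choices: every validation
study runs in minutes on one CPU.  Full-scale ensembles ($10^4$–$2\times
10^4$ realizations, $N=20000$ particles, $\Delta\rho=1.25\times10^{-3}$
reference grids) use the same code with larger arguments.

## What the validation battery does and does not show

The battery exercises exactly the couplings the method is built from:
separable statistics against a closed form; full coupling in the well-mixed
limit against an exact event-driven simulator; full coupling at finite
diffusion against direct functional Fokker–Planck solutions on the same
grid; mass and probability bookkeeping everywhere.  Passing it shows the
engine integrates this class of models correctly at the tested resolutions.
It does not certify accuracy for stiff reaction networks (reactions are
explicit), for particle–particle bimolecular chemistry (not implemented),
or for geometries other than boxes and spheres.

Two statistical limits of the desk-scale studies are worth stating
precisely, because they are properties of the study design, not defects of
the integrator:

* **Error-scaling floor (sparks).**  At $\Delta t=2\,ms$ the discrete
  two-state chain sampled once per step has stationary open probability
  $q_{on}/(q_{on}+q_{off})$ with $q=1-e^{-k\Delta t}$, i.e. $0.16722$
  instead of $1/6$ — a $+0.33\%$ bias worth $\approx0.0125\,\mu M$ in the
  mean spatial average.  This $O(\Delta t)$ truncation error equals the
  statistical error of a $10^4$-realization ensemble, so the fitted
  error-vs-$n$ exponent flattens from $-1/2$ (clearly visible over
  $n=10^2..10^3$) toward $\approx-0.38$ when $n=10^4$ is included.  Only a
  smaller $\Delta t$ moves the floor.
* **Tail visibility (gated binding).**  The relaxation function's power-law
  tail only emerges from under the initial exponential at
  $t\gtrsim13\,\tau_D$, where the asymptote's value is $\approx4\times
  10^{-3}$; the ensemble noise floor at $N\cdot n=62\,400$
  particle-realizations is $\sigma\approx6\times10^{-3}$.  The desk-scale
  run therefore shows the exponential regime and the equilibrium level
  ($C_{eq}\approx N/3$) quantitatively, but a clean measurement of the
  $t^{-3/2}$ exponent requires on the order of $10^7$–$10^8$
  particle-realizations, as in the full-scale configuration.

Known limitations beyond these: particles are points, so fields are
resolved only down to the mesh size around a particle — strong local
depletion (the gated model at fine meshes) is mesh-limited once $h$
approaches the contact radius; the polarization model's cluster-count
diagnostic depends on the documented linkage radius; and the collective
ensemble mode trades per-realization bit-reproducibility for throughput as
described above.
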