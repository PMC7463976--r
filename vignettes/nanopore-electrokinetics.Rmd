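---
title: "Continuum electrokinetics of nanopore translocation: model and numerics"
author: "poreflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrokinetics of nanopore translocation: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

A rigid, negatively charged cylinder with hemispherical end caps — a
continuum surrogate for a short double-stranded DNA fragment, with the
conventional 1 bp = 0.34 nm axial unit — is driven through a nanopore in a
solid membrane separating two electrolyte reservoirs. A DC potential
difference between the outer reservoir walls produces an ionic current
through the pore; the particle's passage perturbs that current (the
resistive-pulse signal) while electrophoresis and electroosmosis set its
translocation speed. `poreflow` solves the fully coupled mean-field model of
this system and reports the two experimentally relevant observables: the
force-free translocation velocity $U_p(y_p)$ and the dimensionless current
deviation $I^*(y_p) = (I - I_0)/I_0$, as functions of the particle's axial
position $y_p$.

## Governing equations

The electrolyte (binary, monovalent KCl at bulk concentration $C_0$) is
described by the Poisson–Nernst–Planck–Stokes system:

- Potential: $-\varepsilon_f \nabla^2 \phi = F(z_1 c_1 + z_2 c_2)$, with
  $\phi = \phi_0$ / $0$ on the top/bottom reservoir walls, surface charge
  $-\mathbf{n}\cdot\nabla\phi = \sigma_p/\varepsilon_f$ on the particle, and
  insulation on the membrane and lateral boundaries.
- Ion transport (steady): $\nabla\cdot\mathbf{N}_i = 0$ with
  $\mathbf{N}_i = \mathbf{u}c_i - D_i\nabla c_i - z_i \frac{D_i F}{RT} c_i
  \nabla\phi$; bulk concentrations on the open walls, zero flux on rigid
  walls, and a purely convective normal flux
  $\mathbf{n}\cdot\mathbf{N}_i = \mathbf{n}\cdot(\mathbf{u} c_i)$ on the
  moving particle surface.
- Flow (creeping): $0 = \nabla\cdot[-p\mathbf{I} +
  \mu(\nabla\mathbf{u}+\nabla\mathbf{u}^T)] + \mathbf{f}$,
  $\nabla\cdot\mathbf{u}=0$, with the Coulomb body force
  $\mathbf{f} = -F(z_1c_1+z_2c_2)\nabla\phi$; no slip on membrane and
  particle ($\mathbf{u} = U_p\hat{\mathbf{y}}$ there), free slip on the
  lateral boundary, and traction-free open top/bottom walls ($p = 0$
  reference).

Forces on the particle are surface integrals of the Maxwell stress
$\varepsilon_p[\mathbf{EE} - \tfrac12 (\mathbf{E}\cdot\mathbf{E})\mathbf{I}]$
and the fluid stress $-p\mathbf{I}+\mu(\nabla\mathbf{u}+\nabla\mathbf{u}^T)$;
the ionic current through a cross-section $S$ is
$I = \int_S F \sum_i z_i \mathbf{N}_i\cdot\mathbf{n}\, dS$.

## The quasi-static position sweep

The translocating particle is inertia-free: it is density-matched (gravity
and buoyancy cancel) and the Reynolds number is vanishingly small, so at
every instant it moves at the velocity where the net axial force vanishes.
Instead of evolving a moving mesh in time, `poreflow` therefore solves a
sequence of steady problems on a fresh boundary-fitted mesh per position and
finds the zero of the axial force over $U_p$ at each one. At fixed charge
fields the Stokes problem is linear in $U_p$, so the axial fluid force is
affine in $U_p$: one extra back-solve on the cached factorisation yields the
drag slope and the predicted force-free velocity, and two or three re-coupled
iterations converge it to the relative tolerance `ff_tol` ($10^{-3}$).
Trajectory time is recovered afterwards as $t(y) = \int dy / U_p(y)$ by
trapezoidal quadrature. The double layer relaxes on the
$\lambda_D^2/D \sim 5$ ns scale while the particle needs microseconds to
advance one Debye length, so the quasi-static picture is self-consistent.

## Geometry, coordinate mode and meshing

The pore has a circular cross-section and the particle is a body of
revolution travelling on the axis, so the default discretisation is
**axisymmetric** over the meridian half-plane $(r, z)$ with the radial extent
$W/2$; a `planar2d` mode (same half-domain, unit Jacobian) is retained for
comparison. The nominal field quoted with the parameter studies is defined as
the average field over the full channel height, $E_{nom} = \phi_0/(2H+h)$,
the only self-consistent mapping between an applied potential and a field
strength for this geometry. The particle length $L_p$ is end-to-end,
including both hemispherical caps.

Meshes are generated internally: boundary curves are sampled at a graded
target size, interior points come from multi-level staggered lattices
selected by the local size field, and a few force-equilibrium (distmesh-type)
relaxation sweeps with Delaunay retriangulation (a compiled Bowyer–Watson
kernel) even out the spacing. The size field keeps edges below a fraction
`bl_frac` of the Debye length within two Debye lengths of the particle and
membrane, below a third of the particle–wall gap inside the pore, and below
$a/2$ next to the caps (curvature control). Low-quality triangles are
repaired by relocating, then dropping, offending interior nodes; generated
meshes satisfy a minimum interior angle of 15 degrees and zero boundary-layer
size violations (checked by `mesh_quality()`). Resolution profiles: `coarse`
(`bl_frac = 0.55`, bulk 14 nm, about 4–6 k triangles, used for sweeps),
`default` (`1/3`, 1.6 nm, about 21 k triangles, matching the element counts
customary for this problem class), `fine` (halved boundary-layer size, for
convergence checks). A particle–wall clearance below $0.15a$ is rejected as a
geometry error rather than meshed.

## Discretisation and solvers

All fields use linear (P1) triangles; the flow uses the MINI element (P1 plus
a cubic bubble per velocity component, P1 pressure), an inf-sup stable pair,
assembled in the symmetric-stress form so that the natural boundary condition
is the true traction — this is what makes the open walls and the free-slip
lateral boundary exact. Equations are scaled internally (lengths in nm,
potential in $RT/F$, concentration in $C_0$, velocity in
$\varepsilon_f (RT/F)^2 / (\mu L_0)$) for conditioning. Volume quadrature is
the interior 3-point rule for scalar operators and a degree-5 7-point rule
for the flow blocks (the bubble terms are quartic); interior-point rules keep
the axisymmetric $1/r$ hoop term finite on elements touching the axis.

The nonlinear coupling is a staggered fixed-point loop with under-relaxation
`relax = 0.5` and relative tolerance `picard_tol = 0.005` on the largest
field change per iteration:

1. **Poisson with Gummel linearisation.** The space charge is linearised
   about the previous iterate, $\sum_i z_i c_i e^{-z_i\Delta\phi} \approx
   \sum_i z_i c_i - (\sum_i z_i^2 c_i)\,\Delta\phi$, which adds a screening
   term to the operator. A bare source-term update is *not* contractive at
   the baseline surface charge (|zeta| about 40 mV) and oscillates
   divergently; the Gummel form converges unconditionally in our runs.
2. **Nernst–Planck per species**, linear in $c_i$ with frozen potential and
   flow. Migration plus convection form the drift; streamline (SUPG)
   stabilisation with the optimal coth rule handles the few cells whose
   drift Peclet number approaches one near the pore mouth. The convective
   surface-flux condition on the moving particle enters as a boundary mass
   term proportional to $U_p n_y$.
3. **Body force and Stokes.** The operator is factorised once per mesh; all
   later iterations and force probes are back-solves.

Cold starts first converge the electrostatic subproblem alone (steps 1–2
with a quiescent fluid): coupling the flow to a far-from-consistent charge
field excites a violent but ultimately bounded transient, and skipping it
costs nothing because the electroosmotic feedback on the ion distributions is
weak at these Peclet numbers. Sweeps warm-start each position from the
previous one (nearest-node field transfer), roughly halving iteration
counts; warm and cold solves agree to well under the Picard tolerance (this
is tested).

## Force evaluation

Two routes are implemented for each force. The production route for the
Maxwell force is the volume (indicator-function) form
$F_E = -\int_V [\mathbf{T}\cdot\nabla\chi + \chi\rho_e\mathbf{E}]\,dV$ with
$\chi$ the P1 indicator of the particle nodes; on an unscreened charged
sphere in a uniform field, where the exact answer is $QE$, it converges to
within a few percent at production resolution. The direct surface quadrature
of $\mathbf{T}\cdot\mathbf{n}$ is kept only as an order-of-magnitude
cross-check: one-sided P1 gradients at a Neumann boundary underestimate the
normal field substantially (a well-known artefact). The hydrodynamic force
uses the consistent reaction of the Stokes system (the residual of the
unconstrained operator at the particle's velocity rows), which is the
discretely exact work-conjugate traction; the direct stress quadrature is
again a rough cross-check. Against the Stokes-drag law for a capped sphere
in a wide anchored reservoir the reaction force is within wall-correction
distance of $-6\pi\mu a U$.

## Observables

The current is evaluated by cutting the mesh with a horizontal plane and
integrating the elementwise axial species flux over the fluid part of the
cross-section (an annulus when the particle straddles the plane — the only
sensible reading when a long particle occupies the pore for most of the
sweep). Discrete conservation makes the reading independent of the plane to
well under 1% at convergence, which is asserted rather than assumed. The
reference current $I_0$ is taken with the particle at its initial position
$(0, -300\,\mathrm{bp})$ — "far from the pore" in the literal sense used by
the parameter studies — and each sweep's $I^*$ is formed against its own
first converged row.

## Verification strategy

No external data enter the tests. Closed-form oracles double as the fixture
generators: Debye length and Nernst–Einstein conductivity (exact arithmetic),
the Grahame relation and Debye–Hückel profile on a one-dimensional slab
(equilibrium double layer), Boltzmann-distributed ion densities, Poiseuille
flow under prescribed traction, Helmholtz–Smoluchowski electroosmotic slip
in a slit (driven by the equilibrium space charge times a tangential field —
exact for a uniform channel and far more robust than driving the ends), the
Stokes drag law, and $QE$ on an unscreened sphere. One calibration detail:
the electrophoretic sanity gate for a 1-nm particle uses the thick-double-
layer spherical surface potential $\zeta = \sigma a/(\varepsilon(1+\kappa
a))$; the flat-plate Grahame value overestimates the potential of so small a
particle several-fold and would misplace any bound built on it.

## Reproduction scope and known limitations

- The coarse-profile sweeps reproduce the qualitative structure of the
  reference field-strength study faithfully: blockade on entry with the
  $I^*$ minimum near $y_p = -92$ bp, enhancement on exit with the maximum
  near $+108$ bp, recovery to $I^* \approx 0$ at $\pm 300$ bp, peak
  velocities ordered and roughly linear in $E_{nom}$, and longer particles
  translocating slower with deeper blockades.
- Computed peak velocities are however systematically higher than the
  reference values (by roughly +24% at 3 MV/m up to +65% at 1 MV/m). The
  package's results are mesh-converged (coarse and production profiles agree
  within 3%), so this is a modelling-chain difference — the coordinate-mode
  and field-mapping ambiguities noted above, and quasi-static sweep versus
  transient moving-mesh — not discretisation error.
- The computed velocity curve at 200 bp has nearly symmetric twin peaks
  (entrance side about 173 mm/s, exit side about 177 mm/s at coarse
  resolution, confirmed at production resolution); the reference study
  reports a single entrance-side peak. The global maximum therefore sits
  near $+88$ bp rather than $-75$ bp.
- In the fully threading regime at the higher drives the coupled steady
  system is bistable: two deep-converged solutions (Picard residual below
  $10^{-7}$) with force-free velocities about 10% apart coexist on the same
  mesh, distinguished by their concentration-polarization state — a known
  hysteresis phenomenon of strongly driven nanoscale electrokinetics. Sweeps
  follow the continuation branch (warm-started from the approach at
  $-300$ bp), which is the branch a transient moving-mesh computation would
  track; isolated cold solves inside the bistable window may land on the
  other branch. Velocity and current orderings across particle lengths
  (50–200 bp) also deviate from the reference study: here the 50 bp particle
  translocates slowest (less driven surface charge at comparable pore drag)
  and the current-deviation depth is not monotone in length, while the
  mid-pore currents across lengths agree to about 9% rather than 5%. The
  reported current-deviation extrema *shrink* mildly with increasing drive
  instead of amplifying. These are model-level differences, reproduced at
  both resolution profiles, and are asserted as-is by the acceptance tests
  (which therefore flag them against the reference expectations).
- Out of scope by design: particle rotation and dielectrophoretic alignment,
  off-axis trajectories, transient double-layer charging, Stern-layer or
  finite-ion-size corrections, and noise/bandwidth modelling of measured
  traces. The data model admits other electrolytes, but only the binary
  monovalent baseline is exercised by the tests.
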