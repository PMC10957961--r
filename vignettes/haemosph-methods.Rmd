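---
title: "Methods: weakly compressible SPH fluid-structure interaction for heart-valve haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly compressible SPH fluid-structure interaction for heart-valve haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

haemosph is a desk-scale solver for cardiovascular flows with moving
structures: a weakly compressible smoothed particle hydrodynamics (WCSPH)
fluid, rigid hinged leaflets for bi-leaflet mechanical heart valves,
a total-Lagrangian SPH scheme for flexible elastic leaflets, and an
SPH-side estimate of wall shear stress from which the clinical risk
metrics TAWSS, OSI, ECAP, PSWSS and the effective orifice area are
derived.  This vignette records the model equations, the numerical
choices that the code makes where the method family leaves them open,
what the shipped fixtures emulate, and the known limits of validity.

## Fluid model

**Kernel.**  All interpolation uses the Wendland C2 kernel
$W(r,h) = \alpha_d (1 - q/2)^4 (2q + 1)$ for $q = r/h \le 2$ and zero
beyond, with $\alpha_d = 3/(4h)$, $7/(4\pi h^2)$, $21/(16\pi h^3)$ in
1/2/3 dimensions.  The smoothing length is tied to the initial particle
spacing, $h = 1.4\,dp$, for fluid and structure alike; the support
radius is $2h$.  Wendland C2 resists particle pairing and integrates to
one over its support (the test suite verifies the normalization by
radial quadrature to $10^{-6}$ and the partition of unity on lattices to
1%).

**Governing equations.**  Particle masses are fixed for the whole
simulation; densities evolve by the SPH continuity equation
$$\frac{D\rho_i}{Dt} = \rho_i \sum_j \frac{m_j}{\rho_j}
  (\mathbf u_i - \mathbf u_j)\cdot\nabla W_{ij},$$
and velocities by the symmetric pressure-gradient form
$$\frac{D\mathbf u_i}{Dt} = -\sum_j m_j
  \frac{p_i + p_j}{\rho_i\,\rho_j}\nabla W_{ij}
  + \Gamma + \mathbf f.$$
The symmetric $\rho_i\rho_j$ denominator is what makes the pairwise
interaction antisymmetric, hence exactly momentum-conserving; the
conservation suite checks global momentum to machine precision in a
periodic inviscid box.

**Dissipation $\Gamma$.**  Two parts: a Morris-type laminar operator
with the physical viscosity ($\mu = 0.003$ Pa s for blood), validated
against the analytic decay rate of a periodic shear wave, and a
sub-particle-scale (SPS) Smagorinsky closure evaluated on the raw SPH
velocity gradient,
$$\mu_T = \rho\,(C_s\,\Delta l)^2 \sqrt{2\,S\!:\!S},\qquad
  \tau = 2\mu_T S - \tfrac23\rho k\,I
  - \tfrac23 C_I \rho\,\Delta l^2\,(2 S\!:\!S)\,I,$$
with defaults $C_s = 0.12$, $C_I = 0.0066$, $k = 0$ and filter length
$\Delta l = dp$.  At the shipped laminar fixtures $\mu_T/\mu \sim
10^{-3}$, so the closure is inert there but participates in the LES-mode
wall shear stress.

**State equation.**  WCSPH closes the system with the Tait/Cole form
$p = (c_0^2\rho_0/\gamma)\,[(\rho/\rho_0)^\gamma - 1]$, $\gamma = 7$,
$\rho_0 = 1060$ kg/m^3.  The numerical sound speed is a design
parameter: `design_sound_speed()` uses the usual rule $c_0 = 10\,U$
against the *largest speed the flow will contain*.  For the valve
fixture that is the transvalvular jet, roughly three times the inlet
peak, not the inlet speed itself -- with $c_0$ set against the inlet
plug the jet raises density fluctuations past the 1% weak-compressibility
contract.

**Time integration.**  One step is kick-drift: velocities are kicked
with the accelerations at the step start, positions drift with the
mid-step velocity.  Densities, however, are integrated with the
*end-of-step* velocities over the frozen step-start pair geometry.  The
distinction matters: updating both $u$ and $\rho$ from the same old
state is explicit Euler on the acoustic $u$--$\rho$ oscillator and
grows grid-scale sound waves at any timestep; staggering them is
symplectic Euler in the acoustic variables and is stable under the CFL
bound.  The timestep is
$\Delta t = \min(0.3\,h/(c_0 + U_{max}),\; 0.125\,h^2\rho_0/\mu,\;
0.25\sqrt{h/|f|})$.

**delta-SPH.**  An optional density-diffusion term (Molteni/Colagrossi
form, coefficient $\delta$) smooths the zigzag density modes that the
continuity equation cannot see.  It is off by default; the channel and
valve fixtures enable it with the standard $\delta = 0.1$, because at
blood viscosity the checkerboard pressure mode is too weakly damped and
grows over $\sim 10^4$ steps.  This is a stabilisation choice made
during fixture design, not a tuned quantity: $\delta = 0.1$ is the
value used throughout the delta-SPH literature.

## Boundaries

**Walls (DBC).**  Walls are three staggered layers of fixed particles.
They never move; their densities evolve by the same continuity equation
driven by fluid neighbours, so approaching fluid compresses the wall
field and feels a repulsive pressure.  Two consequences are important.
First, the wall pressure is floored at zero -- through the monotone
state equation this is implemented as a density floor at $\rho_0$ --
because a rarefied wall would otherwise pull fluid in and, on the
suction side of a moving leaflet, integrate its density to zero.
Second, the no-slip condition is only approximate, which is why wall
shear stress is *not* evaluated at the wall particles (below).
Under streamwise periodicity the staggered layers keep their particle
count and wrap the overhanging particle; dropping it instead leaves a
one-particle gap that destabilises the channel.

**Open boundaries.**  Inlets and outlets are five-layer buffer slabs.
Buffer states are extrapolated from ghost points mirrored into the
fluid with a first-order consistent moving-least-squares fit (exact for
linear fields; verified in the tests), then overridden by the
prescribed data: the inlet prescribes the velocity from the pulsatile
waveform, the outlet prescribes a constant (zero gauge) pressure.
Bookkeeping follows the usual buffer rules: an inlet buffer particle
crossing into the domain becomes fluid and a clone is injected one slab
upstream; fluid that backs into an inlet buffer is removed; fluid
crossing an outlet plane becomes buffer; buffer beyond the outlet's far
edge is removed.

Three regularisations proved necessary at desk resolution and are part
of the boundary design rather than tuning:

* extrapolated buffer densities are clamped to $\rho_0 \pm 10\%$ and
  buffer speeds to $0.3\,c_0$ -- a *fixed* cap; a cap proportional to
  the current flow maximum feeds back on itself and ratchets the flow
  speed up without bound;
* outlet buffers advect as a plug at the mean normal velocity of the
  adjacent interior fluid, outflow only.  Per-particle extrapolated
  velocities at an open end are noisy and re-inject buffer particles;
  and a buffer column faster than the actual discharge drains the slab
  when the outflow stalls (for example the moment the valve closes);
* the prescribed inlet plug is shaped transversely (a 3 dp near-wall
  ramp by default, a parabola in the valve fixture).  A flat plug
  advancing against no-slip walls jams the corner fluid at the first
  systolic acceleration.

**Waveform.**  The inlet waveform is a synthetic parameterisation of a
cardiac cycle: period 0.8 s, a C1-smooth squared-half-sine systolic
pulse peaking exactly at 0.1 s, systole occupying 0.35 of the cycle, a
diastolic plateau at 5% of the peak.  The default peak speed gives a
peak Reynolds number of 7000 in the nominal 25 mm tube
($U \approx 0.79$ m/s with blood properties).

## Rigid leaflet FSI

Fluid loads on a rigid body's member particles are aggregated as
$F = \sum_k m_k f_k$ and $\tau = \sum_k m_k (r_k - R_0)\times f_k$,
with $f_k$ the fluid-exerted acceleration accumulated by the momentum
equation on boundary particle $k$.  A mechanical-valve leaflet has one
degree of freedom: the hinge angle.  Rather than an impulse-based rigid
body engine, the constraint is handled by generalised-coordinate
reduction -- the axial torque about the pivot (parallel-axis transfer
from the centre of mass) drives $\ddot\theta = \tau_{axis}/I_{axis}$,
integrated semi-implicitly; hard stops at 30 and 85 degrees are
perfectly inelastic ($\omega \to 0$ on contact), which matches leaflets
resting at their stops without bounce.  The two leaflets of a valve
open with opposite rotational senses; the hinge carries that sense so
that "opening angle" means the same thing for both.  Member positions
are rotated rigidly, so intra-body distances are preserved to machine
precision, and member velocities are pushed back to the fluid as
$u_k = V + \Omega\times(r_k - R_0)$.  Leaflet structural mass and
inertia are built from the stated leaflet density, 1100 kg/m^3.

## Flexible leaflet FSI (total-Lagrangian SPH)

The elastic solid keeps its reference configuration: neighbour lists
and the kernel-gradient correction matrices $L_i$ (the inverse moment
matrices that make the SPH gradient exact on affine maps) are built
once on the undeformed body.  Each step evaluates the deformation
gradient
$F_i = \big[\sum_j V_j^0 (x_j - x_i)\otimes\nabla^0 W_{ij}\big] L_i$,
the St Venant-Kirchhoff first Piola-Kirchhoff stress
$P = F(\lambda\,\mathrm{tr}(E_g) I + 2\mu_s E_g)$ with
$E_g = (F^TF - I)/2$, and the pairwise, momentum-conserving divergence
$$\frac{dv_i}{dt} = \frac{1}{m_i}\sum_j V_i^0 V_j^0
  (P_i L_i^T + P_j L_j^T)\nabla^0 W_{ij} + g.$$
Solid density follows exactly from mass conservation, $\rho J = \rho_0$.
In two dimensions the Lame constants use the plane-stress reduction
$\lambda_{2D} = 2\lambda\mu_s/(\lambda + 2\mu_s)$, so uniaxial
stretching of a 2D strip reproduces the Young's modulus exactly even at
$\nu = 0.49$.  The SVK law is the minimal finite-strain extension of
the stated linear constants ($E = 1$ MPa, $\nu = 0.49$); whether the
original flexible-valve implementation used SVK or a corotated linear
law is not documentable from the main text, and at leaflet strains the
two coincide to leading order.

The internal force is the exact negative gradient of the discrete
strain energy $\sum_i \psi(F_i)V_i^0$ (verified by finite differences),
so statics are well-defined and free vibration conserves energy (drift
$< 10^{-3}$ over five periods in the tests).  Solid dynamics are stiff
(dilatational wave speed $\sqrt{(\lambda_{2D}+2\mu_s)/\rho_0} \approx
35$ m/s at leaflet constants) and are sub-cycled inside each fluid step
with the fluid coupling frozen.  Coupling mirrors the DBC choice:
solid particles act as boundary particles for the fluid, and the
reaction force is applied back to the solid with the proper mass
conversion.  A small Monaghan artificial viscosity
($\alpha = 0.1$) inside the solid is on by default and switched off for
energy-conservation studies.

Accuracy at desk resolution: the clamped cantilever converges to the
Euler-Bernoulli tip deflection from the soft side, about +13% at 8
particles through the thickness, +11% at 10 and +8% at 12 (root
compliance at the 3-column clamp dominates).  The acceptance check runs
at 12 particles through the thickness.  The first bending frequency is
consistently $\sim 5$--7% low, as expected from the same compliance.

## Wall shear stress and risk metrics

Because DBC walls are imperfectly no-slip, shear is *not* read off the
wall particles.  Instead the velocity gradient is evaluated at the
near-wall fluid band with a kernel-gradient-corrected (first-order
consistent) SPH gradient, using both fluid and wall particles as data
-- the wall's zero velocity is exact Dirichlet data even if the flow
slips past it numerically.  The strain rate $S = (\nabla u + \nabla
u^T)/2$ gives the shear vector as the tangential part of the viscous
traction $2\mu S\hat n$ (laminar mode) or $(2\mu S + \tau_{SPS})\hat n$
(LES mode; the isotropic SPS terms act along the normal and drop out of
the tangential projection, so LES-mode magnitude is never below
laminar).

Transfer to the wall supports two estimators.  The kernel-weighted
average of the last-layer shear over each wall sample's association set
is the literal reading of the near-wall scheme, but it is biased low by
$O(dp/H)$ because the shear profile decays linearly away from a wall.
The default therefore fits a kernel-weighted *linear* model in the
wall-normal coordinate over the near-wall band (2-3 particle rows) and
evaluates it at the wall -- exact for linear shear profiles, and in the
plane-Poiseuille startup it reduces the steady error from about -5% to
-2.6% and keeps the transient within 8% of the series solution beyond
the first tenth of the 0.35 s startup window.

Per wall sample and cardiac cycle (metrics use the last full cycle of
the recorded series; with two simulated cycles this discards the first
as transient):

* TAWSS $= \frac1T\int_0^T |\tau_{wall}|\,dt$ (trapezoidal rule on the
  recorded cadence, default 2 ms);
* OSI $= \frac12(1 - |\int\tau\,dt| / \int|\tau|\,dt)$, the vector
  integral taken componentwise; 0 for unidirectional shear, 0.5 for a
  complete reversal with equal magnitudes, defined as 0 when the
  denominator vanishes;
* ECAP $=$ OSI / TAWSS, undefined (NA, not infinite) at zero TAWSS;
  the conventional safe threshold 0.5/0.36 Pa $\approx 1.39$ 1/Pa;
* PSWSS $= \max_t |\tau_{wall}|$.

The effective orifice area is geometric (planimetric): the valve plane
is rasterised at $dp/2$ and raster points within $0.55\,dp$ of any
solid particle in a $2\,dp$ slab count as blocked.  In 2D the "area" is
the open gap length.  A Gorlin/continuity-equation EOA would need the
pressure recovery model that the underlying method never defines.

## Fixtures: the stated world

All geometries are generated programmatically and deterministically --
identical arguments give bit-identical particle arrays; no randomness
is involved.

* `make_channel_case()`: 2D plane channel, blood properties, 3-layer
  walls; body-force drive (streamwise-periodic, the driving
  acceleration $f = 8\nu U_{max}/H^2$ chosen to reach a target
  centreline speed) or inlet/outlet buffers with the pulsatile
  waveform.  The Poiseuille validation runs at $dp = H/40$.
* `make_bileaflet_valve_case()`: a 2D geometric analogue of a 25 mm
  bi-leaflet valve in a straight tube -- mounting stubs on both walls,
  two 3-layer leaflet plates hinged at 30-85 degree stops (rigid kind)
  or clamped elastic plates at $E = 1$ MPa, $\nu = 0.49$ (flexible
  kind; two leaflets, since a 2D section of the tri-leaflet native
  valve has two cusps).  Hinges sit 3 dp above the stubs so the
  plate's swept circle never scissors fluid against the stub.  It is
  an analogue, not a claim of equivalence to the 3D device.
* `make_cantilever_case()`: clamped-free elastic strip with analytic
  Euler-Bernoulli targets, used to validate the solid scheme without
  fluid.

What a green test establishes: the discretised operators converge on
their analytic limits at the stated resolutions, conservation holds,
and the coupled system reproduces the qualitative leaflet cycle
(closed 30 degrees, opening under systolic inflow, saturation at 85
degrees, return on reversal).  What it does not establish: 3D valve
dynamics, patient-specific geometry effects, turbulence at peak
Reynolds number 7000 (the 2D desk-scale fixtures stay effectively
laminar), or clinical thresholds.

## Known limitations

* DBC slip: near-wall velocities do not vanish exactly; the wall-shear
  estimator compensates but bulk velocity overshoots of a few percent
  remain at coarse resolution.
* The full pulsatile valve cycle at peak systole is stable with
  delta-SPH on, but the open-boundary mass balance drifts by a few
  percent per cycle (outflow plug vs. jet profile mismatch); long
  multi-cycle statistics would need a better outlet.
* The flexible solid's bending stiffness converges from the soft side;
  below ~8 particles through the thickness errors exceed 15%.
* Open-boundary buffers assume straight, axis-aligned boundary planes
  spanning the duct; skew or curved open boundaries are out of scope.
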