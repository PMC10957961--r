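# haemosph

Weakly compressible SPH fluid–structure interaction for heart-valve
haemodynamics, at desk scale, in R.

When a prosthetic heart valve replaces a diseased one, the question that
matters clinically is not only whether the leaflets open and close, but
what the altered flow does to the vessel wall: regions of persistently
low or oscillating wall shear stress promote thrombus formation and
atherogenesis, and high shear damages endothelium. haemosph is for
researchers in computational haemodynamics who want a compact,
fully-inspectable implementation of the particle-based (SPH) route to
these questions: a meshless solver where the valve geometry may move
freely through the fluid, coupled to rigid hinged leaflets (bi-leaflet
mechanical valves) and to flexible elastic leaflets, with the wall-shear
risk metrics computed directly from the particle data.

## The model in brief

Fluid: weakly compressible SPH with the Wendland C2 kernel
(*h* = 1.4 *dp*), continuity `Dρᵢ/Dt = ρᵢ Σⱼ (mⱼ/ρⱼ)(uᵢ−uⱼ)·∇Wᵢⱼ`,
symmetric pressure-gradient momentum equation
`Duᵢ/Dt = −Σⱼ mⱼ (pᵢ+pⱼ)/(ρᵢρⱼ) ∇Wᵢⱼ + Γ + f`, Tait equation of state
(γ = 7, c₀ = 10 × peak speed), Morris laminar viscosity plus a
Smagorinsky sub-particle-scale closure (μ_T = ρ(C_s Δl)²√(2S:S)).
Blood: ρ₀ = 1060 kg/m³, μ = 0.003 Pa·s, Newtonian.

Boundaries: Dynamic Boundary Condition walls (fixed particles whose
density evolves by continuity, giving repulsive pressure); five-layer
inlet/outlet buffer zones with first-order-consistent ghost-point
extrapolation; a pulsatile inlet waveform (period 0.8 s, peak systole at
0.1 s, peak Reynolds number 7000 in the nominal 25 mm tube).

Structures: rigid leaflets reduce to a single hinge angle
(`θ̈ = τ_axis/I_axis`, stops at 30°/85°, inelastic contact); flexible
leaflets use total-Lagrangian SPH with kernel-gradient correction and a
St Venant–Kirchhoff material (E = 1 MPa, ν = 0.49, ρ = 1100 kg/m³).

Risk metrics, per wall sample over a cardiac cycle of length T:

- TAWSS = (1/T)∫|τ_wall|dt
- OSI = ½(1 − |∫τ dt| / ∫|τ| dt) ∈ [0, 0.5]
- ECAP = OSI / TAWSS
- PSWSS = max |τ_wall|; plus a planimetric effective orifice area.

Wall shear is estimated at the last fluid layer adjacent to the wall
(DBC walls are imperfectly no-slip) with a corrected SPH velocity
gradient, then extrapolated to the wall.

## Worked example

Build a wall-shear time series (here analytic, for brevity: sample 1
fully reverses each half-cycle, sample 2 is mostly unidirectional) and
derive the risk maps:

```r
library(haemosph)
T <- 0.8                                   # cardiac period (s)
t <- seq(0, 2 * T, by = 0.002)
rec <- rbind(
  tibble::tibble(sample = 1L, t = t, taux = 1.5 * sin(2 * pi * t / T), tauy = 0),
  tibble::tibble(sample = 2L, t = t, taux = 0.8 + 0.6 * sin(2 * pi * t / T),
                 tauy = 0.2 * cos(2 * pi * t / T)))
ser  <- shear_series(rec, period = T)
maps <- haemodynamic_maps(ser)
maps
#> # A tibble: 2 × 5
#>   sample tawss     osi   ecap pswss
#>    <int> <dbl>   <dbl>  <dbl> <dbl>
#> 1      1 0.955 0.5     0.524    1.5
#> 2      2 0.815 0.00905 0.0111   1.4
```

Sample 1's shear reverses completely, so OSI hits its ceiling 0.5 and
ECAP = 0.5/0.955 ≈ 0.52 1/Pa — the signature of a thrombogenic-prone
site (high oscillation, modest mean shear). Sample 2 is essentially
unidirectional: OSI ≈ 0.01, ECAP ≈ 0.01. TAWSS is the cycle-mean shear
magnitude (2A/π ≈ 0.955 Pa for the pure sine), PSWSS the systolic peak.

The same pipeline runs on the solver: `make_channel_case()` builds the
plane-Poiseuille benchmark (steady wall shear within 5% of the analytic
4μU/H = 1.2 Pa at dp = H/40), `make_bileaflet_valve_case()` the 2D
bi-leaflet valve analogue whose leaflets open from 30° to the 85° stop
under systolic inflow, and `compute_wall_shear()` + `wss_observer()`
record τ_wall during `run_simulation()`. A command-line wrapper with
`run`, `fixtures`, `post` and `validate` verbs is in
`inst/cli/haemosph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/haemosph.R", package="haemosph"))')" \
    validate --suite poiseuille
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch with the installed package (currently the discrete oscillatory
shear index of a fully direction-reversing shear series, evaluated by
trapezoidal integration of 1000 samples over one cardiac period) and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Desk-scale 2D fixtures (plus 3D kernels/operators); patient-specific
aorta geometries, image-based reconstruction and GPU-scale runs are out
of scope. See the methods vignette
(`vignettes/haemosph-methods.Rmd`) for the numerical choices and their
rationale.
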