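---
title: "A coupled multiphase model of bread baking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled multiphase model of bread baking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crumbsim)
```

## The physical picture

Baking dough is a three-phase porous medium: a starch–protein solid network,
liquid water bound in that network, and pore gas (water vapor, CO2 and, late
in the bake, oven air drawn in through the crust). Heat conducted inward
drives a moisture phase change (MPC) that couples everything else:

* While pores are **closed** (below the opening temperature), water moves by
  an evaporation–condensation–diffusion (ECD) shuttle: liquid evaporates on
  the hot pore wall, vapor crosses the pore, condenses on the cold wall and
  diffuses onward through the matrix. Because each crossing carries the
  latent heat, the shuttle also transports heat; it appears in the energy
  equation as an equivalent conductivity and can dominate closed-pore heat
  transfer.
* Closed pores hold their gas, so heating and CO2 release pressurize them.
  The gauge pressure strains the viscous dough — the loaf rises.
* Near the opening temperature the pore walls rupture; gas then flows
  through the connected network (Darcy), CO2 and vapor vent to the oven, the
  pressure difference decays and expansion stops. Moisture exchange switches
  from the equilibrium closed-pore closure to a nonequilibrium rate law.
* The drying surface crusts: water activity collapses, the surface heats
  past the boiling point and its permeability drops an order of magnitude.

`crumbsim` integrates this system on an axisymmetric (r, z) finite-volume
grid (or a reduced 1-D axial column), with the free surface following the
dough through a vertical-Lagrangian moving mesh.

## Governing structure

Per cell the solver tracks extensive masses of solid, liquid, vapor, CO2 and
inert air plus temperature. Mass conservation for each phase carries, as
appropriate: mesh deformation (implicit in the Lagrangian cells), Fickian
liquid diffusion `-rho_s_bar D_l grad W`, the closed-pore ECD liquid flux,
vapor/CO2/air convection with the Darcy velocity and Bruggeman-effective
pore diffusion, and the MPC source. Energy conservation uses a parallel
mixture conductivity plus the closed-pore ECD term

`lambda_eff = f_vs lambda_s + f_vl lambda_l + f_vg lambda_g + (1 - alpha) lambda_EDC f_vg`,

with `lambda_EDC = f_vg D_v,eff a_w L_v/(R T) dP_sat/dT` defined so that
`lambda_EDC grad T` equals the latent heat carried by the ECD liquid flux —
an identity the test suite checks to six digits. `D_v,eff = D_v f_vg^(4/3)`
is the effective (tortuosity-corrected) pore diffusivity; with the free
binary diffusivity instead, the ECD share of conduction computes to well
over 90%, far above the ~60% level the closed-pore analysis supports.

The MPC source relaxes the vapor concentration toward the sorption
equilibrium `a_w(W, T) C_sat(T)` at the rate
`k_MPC = alpha k_open + (1 - alpha) k_closed`: 10 1/s in closed pores (the
equilibrium limit — relaxation is complete within any step) and the fitted
0.8 1/s in open pores.

## Constitutive state functions

Three temperature sigmoids govern the regime transitions; all use a quintic
smoothstep so they saturate *exactly* at their band edges (the stated hard
limits), with zero slope there:

| function | low plateau | high plateau | midpoint | band |
|---|---|---|---|---|
| pore opening `alpha` | 0 (closed) | 1 (open) | 76 °C | 71–81 °C |
| crusting `beta` | 1 (crumb) | 0.1 (crust) | 100 °C | 5 °C wide |
| viscosity `mu_eff` | 1e4 Pa·s | 4.5e6 Pa·s | 80 °C (log-space) | 50–110 °C |

The viscosity sigmoid operates in log space, so its midpoint is the
geometric mean `~2.1e5 Pa·s`. Water activity inverts the Oswin-type
isotherm `100 W = A(T) (a_w/(1-a_w))^B(T)` in closed form; because `A(T)`
vanishes near 156 °C the solver clamps the isotherm's temperature argument
at 110 °C (complete solidification) and extrapolates isothermally above —
without this a hot dry crust would be assigned `a_w ~ 1` and several
hundred kPa of spurious vapor pressure. Saturation pressure uses a Magnus
form `610.78 exp(17.2694 (T - 273.15)/(T - 35.86))` Pa, pinned by the
1 atm ≈ 100 °C check (the coefficients are configurable).

Permeability is `kappa0 alpha^3 beta f_vg^1.34`. The cubic opening gate is
a percolation statement: bulk gas conduction requires a system-spanning
cluster of ruptured pores, so conductivity vanishes superlinearly near the
threshold while the closed (0) and fully open (`kappa0 beta f_vg^1.34`)
limits are untouched. The same cubic gate and the crust factor apply to
pore-gas diffusion. With a linear gate, cells barely into the opening band
already leak at ~10% of the open conductance, which prematurely vents the
band (observed as a loss of the closed-pore pressure signal) and lets the
band act as a condensation cold trap.

### CO2 source

The CO2 generation correlation (linear below 40 °C, Gaussian decay above,
with its 0.2% branch mismatch at the seam resolved in favor of the Gaussian
branch) is printed without a time base. Taken as kg/(kg·s) it would
generate several kg of CO2 per m³ of dough over a bake — an order more gas
than a loaf can hold. The source therefore carries a normalization
`k_co2_scale = 0.2`, chosen so the integrated release matches the
desorbable dissolved-CO2 inventory of fermentation-saturated dough
(Henry's law: ~1.35 g CO2 per litre of liquid near 30 °C, times the 48%
liquid volume fraction, ≈ 0.65 kg/m³). This is a physical-budget argument,
fixed before any simulation of the reference scenario.

## Mechanics

The dough is confined by the mold (no-slip bottom, frictionless side walls,
free top), so deformation is vertical and the momentum balance reduces to a
column-wise extensional creeping flow: each cell's volumetric strain rate is

`e = (P_g - P_amb - overburden) / ((4/3) mu_eff + (P_g/f_vg) dt)`,

the balance of the closed-pore gauge pressure against the extensional
viscous stress (the `4/3` is the uniaxial value of the compressible
Newtonian stress); the second denominator term is a semi-implicit
linearization of the gas stiffness, exact as `dt -> 0`. Positive strain is
weighted by `(1 - alpha)`: only closed pores push the matrix — once the
network interconnects, gas vents through it rather than straining the
walls, and expansion ceases at full opening, which is also what the
height-plateau observations show. Radial shear coupling between columns is
neglected (slender-column approximation); the axis and edge of the loaf
still rise differently because their thermal histories differ.

Guards that encode physics the viscosity sigmoid alone misses: dried cells
(`W < 0.05`) are rigid (moisture loss completes solidification); compression
is capped at 1e-4 1/s (the cell-wall network resists buckling — observed
post-expansion settling is a fraction of a millimetre, strain rates around
2e-5 1/s); pores cannot be squeezed below 5% porosity; a single cell may
not stretch past four times its initial spacing; columns stop at the mold
lip. An alternative `prescribed_divergence` closure (divergence imposed
from the local ideal-gas volume balance) is available for comparison.

## Numerics

The outer explicit loop (adaptive step, bounded by the conduction stability
limit and a 2% volumetric strain per step) advances mechanics and mesh
motion, energy conduction with boundary fluxes, liquid transport and the
CO2 source. Transported liquid carries its volume: a cell receiving
condensate swells instead of compressing its pore gas. Fast gas physics is
subcycled (0.1 s substeps): the vertical Darcy system is solved implicitly
in pressure (backward Euler, one tridiagonal solve per column via a
vectorized Thomas algorithm) so venting and pressure equilibration
propagate through whole columns within a substep; species masses move along
the implicit fluxes with donor-cell composition; binary diffusion acts on
the post-Darcy composition (computing it from pre-equilibration densities
would double-count the pressure-driven transport); radial Darcy flow is
explicit with an overshoot cap at the pressure-equalizing volume. Phase
change is a linearized saturation adjustment — the vapor mass whose
transfer brings concentration and temperature jointly to the sorption
equilibrium, including the latent shift of `C_sat` — applied at the
nonequilibrium rate; evaporation cools toward the wet-bulb point and
condensation heats toward the dew point without overshoot. Positivity is
preserved by scaling each cell's outgoing fluxes to at most 95% of its
content, monotone upwind donor fluxes handle the sharp fronts, and
condensation may not push porosity below 2%. Solid mass is conserved
exactly; the global water budget closes to machine precision and is
audited every run.

Default resolutions: the 2-D reference runs use 10 radial × 20 axial cells
(level 2; level `n` sets `2 + 4n` columns of `8 + 6n` cells), the 1-D
axial mode one column. Boundary-layer grading is not applied by default.

## The oven model

The default program is a constant 180 °C air temperature with the mold wall
following a first-order lag (250 s time constant, starting at the dough
temperature) and an effective radiation density of 1000 W/m². A synthetic
oscillating program (`synth_oven_program()`) emulates intermittent-heating
traces: a deterministic-for-seed, mean-zero triangular oscillation about
the setpoint with the wall as its low-pass. Surface mass transfer uses the
Chilton–Colburn analogy `h_m = h_c/(rho_air c_p,air Le^(2/3))` with species
Lewis numbers; oven humidity defaults to 0.5 mol/m³ (hot dry oven) and
oven CO2 to zero. The top face collects convection, net gray-surface
radiation `epsilon (Phi - sigma T^4)` and evaporative cooling; mold faces
conduct at the contact coefficient 100 W/(m²·K).

## What the synthetic scenario does and does not emulate

The generator reproduces the study conditions — geometry (50 mm radius,
20 mm initial height, 100 mm mold), initial state (28 °C, dry-basis
moisture 0.82, density 1069 kg/m³, pore gas closing ambient pressure with
fermentation CO2), oven program and the fitted transition parameters. It
does not emulate measured oven oscillation traces (not tabulated; the
constant-setpoint program stands in, which is why reproduction tolerances
are of the "approximately" grade), oven cavity radiation geometry, dough
recipe variability, or crust browning chemistry (explicitly out of scope;
the associated kinetic constants appear in no governing equation and are
left unimplemented). Passing tests therefore demonstrate internal
consistency and desk-scale reproduction of the calibrated scenario, not
predictive accuracy for other ovens or recipes.

## Known limitations

* The volumetric closure linking matrix pressure to gas pressure is the
  model's main open gap (the source analysis solved it inside a commercial
  fully coupled FEM without stating the equation of state); the
  `pressure_driven` and `prescribed_divergence` closures bracket plausible
  readings. Quantities tied tightly to that closure — the closed-pore
  pressure trace and the late-bake drying rate — carry the largest errors.
* Under strict ideal-gas accounting with pore pressure closed at ambient,
  the closed-pore vapor mole fraction `P_v/(P_v + P_CO2)` is bounded by
  `a_w P_sat(81 °C)/P_amb ≈ 0.48` before full opening; reported values
  near 70–80% are not reachable by any parameter choice in this closure,
  and the corresponding composition diagnostics sit below them.
* Radial shear, surface tension, viscoelasticity and pore-scale rupture
  mechanics are not modelled (the opening sigmoid subsumes them).
* The sorption isotherm and CO2 correlation are extrapolated outside their
  calibration ranges with the documented clamps.
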