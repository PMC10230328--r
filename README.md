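# elastocg

Coarse-grained elastohydrodynamics of filaments and sphere-built bodies in R.

`elastocg` simulates collections of three-dimensional inextensible elastic
filaments (Kirchhoff rods: bend and twist, no stretch or shear) together with
rigid bodies of arbitrary shape, all built from spheres and coupled
non-locally through Stokes-flow hydrodynamics. It is aimed at cell-scale
biophysics: cilia and flagella, sperm and bi-flagellate swimmers, filament
relaxation and actuation, and passive tracer transport.

## The method in one paragraph

Momentum balance is integrated over rigid units instead of being solved as a
high-order PDE. For every structure the package assembles a total force
balance, a total torque balance, and — for each filament joint `s_j` — the
moment balance integrated from the joint to the tip,

```
sum_{k beyond j} [ (y_k - x_j) x F_k + T_k ] = -m_j - int_{s_j}^{L} m_a ds ,
m_j = Eb (k1 - k1^0) d1 + Eb (k2 - k2^0) d2 + Et (k3 - k3^0) d3 ,
```

collected as `M_F [F; T] = K`. The Rotne–Prager–Yamakawa grand mobility
closes the system (`[V; Omega] = M_H [F; T]`, unequal radii, rotation–
translation coupling, an overlap-regularized variant that stays
positive-definite at zero separation), and rigid-chain kinematics `Q` reduce
the unknowns to body velocities plus segment angular velocities. Segment
orientations are tracked by the exponential map of quaternions
(`q = exp(r)`, `omega = 2 D(r) rdot`, with the `|r| >= pi/2` rescaling that
keeps `D` invertible), giving a stiff ODE system

```
M_F M_H^{-1} Q D  Xdot = K ,   X = (x_b, r_b, r_2, ..., r_N, ...)
```

integrated by an adaptive BDF solver; a direct quaternion backend
cross-validates every rotation-handling choice. Force-free swimming,
kinematic base constraints (replace force/torque rows by prescribed
`xdot_1(t)`, `rdot_1(t)`), preferred-curvature drives `k^0(s,t)` and active
moment densities `m_a(s,t)` are all supported. Everything is dimensionless:
lengths in filament lengths `L`, unit viscosity, unit drive frequency, and
stiffness through `S^4 = L^4 eta omega / Eb`.

## A worked example

A filament bent into a semicircle relaxes back to a straight line while its
centre of mass stays put:

```r
library(elastocg)
# 10 rigid segments, 2 spheres per segment, stiffness parameter S = 3
scn <- scenario_relaxation(N = 10, n = 2, S = 3, tend = 5, nout = 6)
res <- run_scenario(scn)
print(res$trajectory)
#> ehd_trajectory: 6 output times on [ 0 , 5 ], backend expmap
#>   steps: 202  rejected: 0  fevals: 547  jacobians: 1  rescalings: 0
str(res$measurements)
#> List of 2
#>  $ com_drift          : num 0.028
#>  $ final_max_curvature: num 0.0287
```

`com_drift` is the largest excursion of the centre of mass over the run
(0.028 L here; a force-free filament must not swim, and the residual drift
shrinks with resolution — 0.019 L at the published N = 40 discretization).
`final_max_curvature` shows the shape is nearly straight by `t = 5` and
still unbending. The elastic energy `Eb/2 sum (kappa - kappa^0)^2 ds` decays
from 0.067 at `t = 0` to 2e-6 at `t = 5`:

```r
elastic_energy(scn$system, trajectory_state(res$trajectory, 1))  # 0.067
elastic_energy(scn$system, trajectory_state(res$trajectory, 6))  # 2e-06
```

Other ready-made scenarios (each with the published parameters as defaults):
`scenario_helical()` (rotated, tilted base), `scenario_swimmer()` (undulatory
swimmer, single or hydrodynamically coupled pair), `scenario_chlamydomonas()`
(bi-flagellate puller with full/reduced coupling and out-of-plane curvature),
`scenario_sperm_egg()` (active-moment sperm scattering off a free egg) and
`scenario_cilia_array()` (metachronal cilia over a sphere-built wall, with
passive tracers). Lower-level building blocks — `filament()`,
`build_spherical_body()`, `build_wall()`, `ehd_structure()`, `ehd_system()`,
`rpy_mobility()`, `ehd_integrate()`, `kinematic_constraint()` — compose
arbitrary multi-filament/body systems.

## Command line

```sh
Rscript inst/exec/elastocg relax --N 10 --n 2 --S 3 --tend 5 --out out/run1
Rscript inst/exec/elastocg --help
```

Subcommands: `relax`, `helix`, `swim`, `chlamy`, `sperm-egg`, `cilia`; any
`--key value` overrides a scenario parameter; `--config file.json` loads a
saved run configuration; trajectories and measurements are written as
tab-separated text.

## Notes

* The solver suite (unit, property and acceptance tests) is deterministic:
  no random numbers are used anywhere in the core.
* Runtime grows steeply as `S` drops below ~1 (very stiff filaments); the
  published scenarios use `S` between 1.5 and 6 and run in seconds to a few
  minutes each at the published resolutions.
* Out of scope: lubrication corrections, steric/adhesive/Brownian forces,
  Cosserat extensibility/shear, wall-image mobilities (walls are built from
  spheres instead).
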