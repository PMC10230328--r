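---
title: "Coarse-grained elastohydrodynamics of filaments and sphere-built bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained elastohydrodynamics of filaments and sphere-built bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`elastocg` simulates collections of inextensible, unshearable elastic
filaments (Kirchhoff rods, supporting bend and twist) and rigid bodies, all
immersed in an inertialess viscous fluid and coupled non-locally through
hydrodynamic interactions. Everything is built from spheres: a rigid body is
a set of spheres moving as one frame, and a filament is a chain of $N$ rigid
segments of $n$ touching spheres each, with segment length $\Delta s = L/N$.

A filament is described by its centreline $x(s)$, $s \in [0, L]$, and an
orthonormal director basis $[d_1(s), d_2(s), d_3(s)]$ with $d_3$ tangent.
Arclength derivatives of the directors define the twist vector
$\kappa = \kappa_1 d_1 + \kappa_2 d_2 + \kappa_3 d_3$ through
$\partial_s d_i = \kappa \times d_i$; $\kappa_1, \kappa_2$ are bending
curvatures and $\kappa_3$ the twist density. Discretely, each segment $i$
carries its own director basis and the endpoints follow
$x_i = x_1 + \Delta s \sum_{j<i} d_3^j$, so the chain is exactly
inextensible by construction — no Lagrange multipliers, no constraint drift.

Instead of solving the high-order moment-balance PDE, the momentum balance
is integrated over rigid units. For each structure this yields

* a total force balance over all its spheres,
* a total torque balance about the body origin $x_b$, and
* for every interior filament joint $s_j$ ($j = 2..N$), the moment balance
  integrated from $s_j$ to the tip:
  $\sum_k \left[(y_k - x_j)\times F_k + T_k\right] = -m_j - \int_{s_j}^{L} m_a\, \mathrm{d}s$,
  the sum running over that filament's spheres beyond the joint.

Here $F_k, T_k$ are the force and torque the fluid exerts on sphere $k$, the
constitutive bending moment is
$m_j = E_b(\kappa_1 - \kappa_1^0) d_1 + E_b(\kappa_2 - \kappa_2^0) d_2 + E_t(\kappa_3 - \kappa_3^0) d_3$,
$\kappa^0(s, t)$ is a preferred-curvature drive and $m_a(s, t)$ an active
moment density. Collected over all structures this is the linear block system
$M_F [F; T] = K$.

Hydrodynamics closes the system: the Rotne–Prager–Yamakawa (RPY) grand
mobility maps forces and torques on all $M$ spheres to their velocities,
$[V; \Omega] = M_H [F; T]$, including translation–rotation coupling and
unequal radii. Rigid-chain kinematics reduce the unknowns to
$W = (\dot x_b, \omega_b, \omega_2, \dots, \omega_N)$ per structure via
$[V; \Omega] = Q W$ (clamped filaments share $\omega_1 = \omega_b$), giving
the governing system

$$ M_F M_H^{-1} Q\, W = K. $$

Orientations are tracked by generators $r$ (exponential map of quaternions,
$q = \exp(r) = (\cos|r|, \operatorname{sinc}|r|\, r)$, a rotation by $2|r|$):
$\omega = 2 D(r) \dot r$ turns the governing system into a square ODE
$M_F M_H^{-1} Q D_{blk}\, \dot X_{gen} = K$ for the state
$X_{gen} = (x_b, r_b, r_2, \dots)$. Since $\det D = \operatorname{sinc}^2|r|$
vanishes at $|r| = n\pi$, any generator reaching $|r| \ge \pi/2$ is rescaled
between integrator steps to $r - \pi r/|r|$ (the same rotation, opposite
quaternion sign). A direct quaternion backend
($\dot q = C(q)\,\omega$, one extra coordinate per rotation) is kept for
cross-validation; both backends must agree in sphere positions to
integration tolerance, and the test suite asserts this.

## Dimensionless conventions and parameters

Lengths are in filament lengths $L$, the viscosity is $\eta = 1$, drives
oscillate at unit angular frequency (period $2\pi$), and stiffness enters
through the dimensionless stiffness parameter $S^4 = L^4 \eta \omega / E_b$,
implemented as $E_b = E_t = 1/S^4$. Preferred curvatures are in $1/L$ and
active moment densities in $E_b/L^2$ (the drive amplitude supplied by the
user is multiplied by $E_b$ internally). The sperm number reported for the
helical-actuation scenario uses
$\mathrm{Sp}^4 = \left[4\pi / (\log(L/a) + 0.5)\right] S^4$ with $a$ the
filament sphere radius. Typical biological regimes have $S$ between 1
and 20; lowering $S$ (stiffer filament relative to viscous loading) makes
the ODE system markedly stiffer and slower to integrate.

Key geometric defaults (all configurable):

* filament sphere radius $a = \Delta s / (2n)$ — adjacent spheres touch on a
  straight filament;
* spherical bodies are Fibonacci-lattice shells with per-sphere radius half
  the minimum nearest-neighbour distance (approximately touching, never
  overlapping);
* walls are monolayers of touching spheres, held fixed (no degrees of
  freedom; their balance rows are dropped and the wall absorbs momentum).

## Numerical choices

**Curvatures.** Discrete curvatures at joint $j$ use joint-centred
differences of the two adjacent segment bases with the normalized average
basis as projection frame, e.g.
$\kappa_1 = (\Delta d_2/\Delta s) \cdot \bar d_3$. The scheme is second-order
(verified against analytic circle and twist fields) and frame-covariant.
Whether the source formulation evaluates curvature at joints or midpoints is
not stated; joints were chosen. Preferred curvatures are evaluated at the
joint arclengths $s_j = (j-1)\Delta s$, measured from the base.

**Active moment integrals.** $\int_{s_j}^{L} m_a\,\mathrm{d}s$ is computed
per segment with the directors frozen within each rigid segment; the
sinusoidal family `active_moment_wave()` integrates in closed form, generic
callables use 4-point Gauss–Legendre per segment.

**RPY tensors.** Dense $6M \times 6M$ storage and Cholesky solves — every
published scenario has at most a few hundred spheres. Unequal radii are
supported in all blocks. The overlap-corrected variant (continuous at the
region boundaries, positive-definite down to zero separation, verified to
machine precision in the tests) is selected by every scenario builder,
because a touching-sphere filament necessarily overlaps slightly across
joints whenever it bends; for separated pairs it coincides exactly with the
standard tensors. The corrected branch takes over only once the overlap
exceeds a relative margin of $10^{-4}$: the branches agree to
$O(\text{overlap}^2) \approx 10^{-8}$ there, and keeping exactly-touching
spheres on the smooth standard branch avoids parking the dynamics on the
(merely $C^1$) formula switch. With `overlap_corrected = FALSE`, meaningful
overlap is an error naming the offending pair.

**Stiff integration.** The environment provides no stiff ODE solver, so the
package carries a compact adaptive variable-order BDF(1-3) integrator
(`ode_bdf()`): the variable-step BDF formulas come from the derivative of
the Lagrange interpolant through the new node and the recent history, with
modified Newton, finite-difference Jacobians reused until convergence
degrades, a weighted-RMS solution-difference error controller, cubic
Hermite dense output, and an event hook for generator rescaling (which
restarts the multistep history at order 1). Hard-won stability details:
the Newton iteration stops at $10^{-2}$ of the local tolerance with a
rate-based criterion (looser stops leave fast-mode noise on the history
nodes that stalls the controller); order-1 steps estimate their error by
step doubling (the implicit/explicit-Euler difference saturates for stiff
modes); and at order 3 the step-ratio growth is capped at 1.3 with an
order drop after any rejection, because variable-step BDF3 tolerates only
mild step-ratio variation -- without this the driven scenarios destabilize
mid-run. Default tolerances are rtol $10^{-6}$, atol $10^{-8}$; halving
them changes relaxation endpoints below $10^{-5}$ (asserted in the tests).
Very stiff configurations (helical actuation at $\mathrm{Sp} \lesssim 1$)
sweep a broad cascade of relaxation rates and pin the step size near the
stability scale of the fastest elastic mode; such runs remain slow (the
source study makes the same qualitative remark about small $S$), and the
stiff-limit behaviour is therefore tested at feasible sperm numbers
(rigid-rod bound plus the monotone tip-distance trend) rather than in the
impractical true limit.

**Constraints.** Kinematic constraints replace a structure's force and/or
torque balance rows by prescribed $\dot x_1(t)$ or $\dot r_1(t)$ rows on the
reduced coordinates. The quaternion backend converts a prescribed generator
rate through $\omega = 2 D(\log q)\, \dot r$ at the current orientation
(principal logarithm), which is exact while $|r| < \pi/2$ — the regime of
the published helical drive.

## What the scenarios state, and what was not printed

The six scenario builders reproduce the published set-ups with their printed
parameters as defaults (asserted against a frozen table in the tests):
relaxation ($N = 40$, $n = 2$, $S = 3$, semicircle initial condition,
$t \in [0, 20]$), helical actuation ($N = 20$, $n = 1$,
$\alpha_0 = 0.2618$, $\delta_0 \in \{0.1, 0.02\}$), undulatory swimmers
($N = 16$, $n = 1$, $S = 22.6^{1/4}$, piecewise amplitude
$K_0 = 8.25$ for $s \le L/2$, $16.5(L-s)/L$ beyond), the bi-flagellate
puller ($N_{body} = 184$, $R = 0.35$, $2\theta = 23°$, $N = 15$, $S = 3$,
$\kappa^0 = \pm 4[1 + \sin(2\pi s - t)] d_2$ plus optional out-of-plane
$\kappa_1^0 d_1$), sperm–egg scattering (head $0.2L$, egg $1L$, $N = 16$,
$S = 6$, $m_a = 12k\cos(ks - t) d_2$, initial separation $5L$) and the
cilia array ($5\times5$ grid, $N = 7$,
$\kappa^0 = (1 + 5\sin(1.5\pi s - t + \phi)) d_1$,
$\phi = (\mathrm{row}-1)/\mathrm{rows}\cdot 2\pi$, tracer radius $0.01L$).

Decisions where the sources are silent:

* **Swimmer wavenumber $k$.** Not printed. The measured distance per stroke
  is strongly $k$-sensitive (0.055 at $k=\pi$ to 0.083 at $k=2\pi$), so the
  choice matters. The drive models the much-studied undulatory gait of
  *C. elegans*, whose measured swimming wavelength is about $1.54$ body
  lengths; the default is therefore $k = 2\pi/1.54$. With it the single
  swimmer travels $0.0717\,L$ per stroke versus the published $0.0671\,L$
  (+6.9%). No attempt was made to fit $k$ to the published number.
* **Sperm-drive wavenumber.** Also unprinted; one wavelength per flagellum
  ($k = 2\pi$) is typical of sperm and is the default.
* **Cilia stiffness.** $S$ is not printed for the cilia array; $S = 3$ (the
  value used for the other driven scenarios) is the default. Cilia spacing
  ($0.5L$) and wall sphere size ($0.2L$ diameter) are read off the published
  figure scale.
* **Body packings and radii.** The sphere layouts of the published bodies
  are not stated; Fibonacci shells are used. The sperm head is a single RPY
  sphere; the egg is a 128-sphere shell by default. The shell is not
  optional physics: a force- and torque-free *single* RPY sphere scatters no
  flow at all (in the mobility formulation it merely advects), so a
  single-sphere egg is hydrodynamically invisible to the swimmer and cannot
  produce the published speed modulation. Only a sphere-composite egg blocks
  and deflects the flow.
* **Cilium orientation.** The published drive
  $\kappa^0 = (1 + 5\sin(1.5\pi s - t + \phi))\, d_1$ leaves the clamp
  orientation (which way $d_1$ points in the lab) unstated. The builders use
  a half-turn about $z$ so the positive mean curvature bends the cilia
  toward $+y$; with the identity clamp the same drive pumps fluid along
  $-y$, antiparallel to the metachronal wave, whereas the published array
  transports along the wave ($+y$). The height-decay of transport is
  orientation-independent.
* **Circular-path scaling.** With symmetric out-of-plane curvature
  $\kappa_1^0$ on both flagella the bi-flagellate swims in circles. The
  turning rate is odd in $\kappa_1^0$ (the $\kappa_1^0 = 0$ baseline is the
  published straight path), so the quantity that grows linearly with
  $\kappa_1^0$ is the path curvature $1/r$; the radius itself is inversely
  proportional (measured turn per stroke 0.019/0.030/0.037 at
  $\kappa_1^0 = 0.3/0.5/0.7$). The acceptance test asserts linearity of
  $1/r$.
* **Pair swimmers.** The published pairs start from the single swimmer's
  steady state, which `scenario_swimmer(init_state = ...)` supports (for an
  anti-phase pair, pass the solo state half a drive period earlier for the
  second swimmer). This matters: a straight side-by-side start kicks the
  in-phase pair toward each other hard enough that, with no steric forces in
  the model, the filaments eventually interpenetrate and tangle. With the
  published protocol the orderings (in-phase slower than solo, anti-phase
  faster) emerge within two periods.

## What the generator emulates — and what a green test does not establish

The scenario builders double as the synthetic-data generator for the test
suite: every input is constructed programmatically from printed parameters;
there is no randomness anywhere in the core (identical configs give
bit-identical trajectories). Scaled-down configurations (smaller bodies,
shorter runs, relaxed tolerances) are used for the ordinal figure-level
checks to stay within test-time budgets; they preserve the printed drives
and mechanisms but not the published system sizes, so those green tests
establish orderings and trends, not figure-level numbers. The RPY
approximation itself is a far-field pair approximation: lubrication at
near-contact, steric repulsion, adhesion and Brownian noise are all outside
the model (the governing-system interface accepts additional state-dependent
forces on its right-hand side, but none are implemented).

## Known limitations

* BDF order is capped at 2; very stiff runs ($S \lesssim 1$, or helical
  actuation at small Sp) are slow. The published study used a higher-order
  stiff solver and reports the same qualitative slowdown at small $S$.
* The quaternion backend supports rotational kinematic constraints through
  the principal logarithm only (sufficient for the published drives).
* Fixed bodies must be genuinely immobile (the wall); there is no prescribed
  time-dependent rigid body motion other than through base constraints.
* Measurements that require periodic steady state detect it from the last
  two periods (0.1% for swimmers, 0.5% for tip distances); runs that have
  not converged report `steady = FALSE` rather than failing.
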