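---
title: "Methods: reduced-order bioreactor hydrodynamics and perfusion seeding"
author: "tracheoseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order bioreactor hydrodynamics and perfusion seeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracheoseed)
```

## The system being modelled

A de-epithelialized tracheal scaffold (a tube of radius $R = 6.35$ mm,
length $L = 3$--$10$ cm, default 5 cm) is mounted horizontally between two
anchors inside a double-chamber bioreactor. Culture medium is perfused
through the lumen at $Q = 1.5$ mL/min while the scaffold rotates about its
axis at 0--30 rpm. During perfusion cell seeding, a bolus of suspended
epithelial cells ($d_p = 10\ \mu$m, $\rho_p = 1050$ kg/m$^3$) is injected
upstream; cells are carried by the flow, settle under gravity, and attach
where they touch the lumen wall. Two fluid-delivery designs are supported:
a *single rotating inlet* (entry port and inlet anchor co-rotate with the
scaffold) and a *double static inlet* (annular entry through a fixed anchor,
scaffold rotates around it). The outlet anchor is static in both.

Two questions drive the package: what wall shear stress (WSS) environment do
the operating conditions impose on the lumen, and where do the injected
cells deposit?

## The composite flow model

At these conditions the diameter Reynolds number is
$\rho \bar u D/\mu \approx 2.5$ ($\bar u = Q/\pi R^2$): creeping flow. The
package therefore replaces a full 3-D CFD solution with a reduced-order
composite field in cylindrical coordinates $(r, \theta, z)$:

* **Axial**: fully developed Poiseuille flow
  $u_z(r) = (2Q/\pi R^2)\,(1 - (r/R)^2)$, independent of $z$. The creeping
  entrance length is under one radius, so axial development is neglected.
* **Radial**: $u_r \equiv 0$. Meridional secondary flow (for example
  Ekman-type pumping at rotating/static interfaces) is out of scope — a
  consequential limitation discussed below.
* **Azimuthal**: a developing swirl field $w(r, z)$ solving the linear
  advection--diffusion reduction of the azimuthal momentum balance,
  $$ u_z(r)\,\frac{\partial w}{\partial z}
     = \nu\left(\frac{\partial^2 w}{\partial r^2}
     + \frac{1}{r}\frac{\partial w}{\partial r} - \frac{w}{r^2}\right), $$
  marched implicitly in $z$ (second order in $r$, first order in $z$,
  axially graded grids after each wall-condition change) from a zero-swirl
  inflow. The wall moves at $\Omega R$ on rotating spans and is static on
  anchor spans; which spans rotate is exactly what distinguishes the two
  inlet designs. A single global sparse solve of the identically discretized
  problem serves as an independent verification route, and a slab-limit
  similarity solution (erfc profile) checks the physics of the marching
  scheme against a closed form.

Axial and azimuthal momentum decouple in this regime, which is what makes
the composite construction consistent: swirl is a passively developing field
superposed on the through-flow.

### Wall shear stress: which gradient is reported

`wall_shear()` reports, per axial station,
$\tau_{ax} = \mu |du_z/dr|_{r=R}$,
$\tau_{az} = \mu |\partial w/\partial r|_{r=R}$ (the lab-frame wall velocity
gradient), and $\tau = \sqrt{\tau_{ax}^2 + \tau_{az}^2}$, with an
area-weighted min/max/mean over the scaffold span.

The choice of $\tau_{az}$ deserves a note. The true azimuthal viscous
traction on the wall is $\mu|\partial w/\partial r - w/r|$, which vanishes
identically once the swirl reaches solid-body rotation. General-purpose CFD
post-processors instead report the magnitude of the tangential velocity
gradient at the wall, which tends to $\mu\Omega$ in solid-body rotation —
and the published WSS averages for this device scale exactly as
$\mu\Omega$ (e.g. $1.5\times10^{-3}$ Pa at 15 rpm
$= \mu \cdot 2\pi\cdot 15/60$). To be comparable with those figures the
package reports the lab-frame gradient as `tau_azimuthal_Pa` and exposes the
true traction separately as `tau_azimuthal_traction_Pa`. Users interested in
the mechanical stimulus of a *co-rotating* cell layer should look at the
traction column; users comparing against reference WSS maps should use the
default.

With this convention the model reproduces, with no fitted constants:
0 rpm $\to 4\mu Q/\pi R^3 = 1.243\times10^{-4}$ Pa (analytic);
1 rpm $\to 1.63\times10^{-4}$; 5 rpm $\to 5.38\times10^{-4}$;
15 rpm $\to 1.58\times10^{-3}$ Pa — each within a factor 1.1--1.3 of the
published full-CFD averages for the single-inlet design, and the mean WSS at
the recommended seeding point (1 rpm, 1.5 mL/min) stays below the
$2\times10^{-4}$ Pa ceiling recommended for seeding.

### Numerical choices

* Radial grid uniform on $[0, R]$ (the tracker exploits this); axial grid
  graded toward each wall-condition discontinuity with exponent 1.6.
* Wall derivatives by one-sided second-order stencils; exact for the
  parabolic $u_z$, so the 0-rpm summary is grid-independent to rounding.
* Boundary nodes exactly at a rotating/static interface are assigned to the
  rotating scaffold, keeping the singular corner just outside the averaging
  span. The double-static design has its corner at the scaffold inlet, i.e.
  *inside* the span: its mean WSS converges under refinement (< 1% on grid
  doubling) but its *maximum* WSS grows without bound as the grid resolves
  the corner singularity — the same sensitivity the reference mesh study
  reported as a 5--10% maximum-shear change between meshes. Grid-convergence
  assertions therefore target the default (single-inlet) configuration.

## Particle transport

Cells are inert spheres with Stokes drag. The momentum relaxation time
$\tau_p = \rho_p d_p^2 / 18\mu \approx 5.8\,\mu$s and settling speed
$v_s = (\rho_p - \rho) g d_p^2/18\mu \approx 2.7\,\mu$m/s give a Stokes
number far below one, so the default integrator uses the overdamped
equilibrium closure
$$ u_p = u + v_s \hat g + \tau_p \frac{w^2}{r}\,\hat r, $$
(drag equilibrium plus gravitational drift plus the centrifugal slip from
the curved streamlines), advanced by RK4 in Cartesian coordinates with the
protocol path step (1 mm) *and* an angular step cap of 0.1 rad. The angular
cap matters: explicit schemes that take a full millimetre step through
near-solid-body swirl acquire a systematic outward radius drift that would
counterfeit centrifugal deposition. With the cap, the spurious drift is
below $10^{-6}$ relative per orbit.

The guard on this closure is `mode = "full"`: the inertial momentum equation
integrated with an exponential--trapezoidal (ETD2) scheme that solves the
linear drag exactly while treating the fluid velocity as linear in time over
each step. Treating the field as *frozen* per step would silently lose the
$O(\tau_p)$ slip (the response $-\tau_p\,Du/Dt$ appears only through the
time variation of $u$ along the path); the ETD2 form retains it. At 0 rpm
the two integrators agree in trap position to tens of microns and
hundredths of a degree. Under rotation, particles captured from long
orbiting trajectories show trap-*angle* scatter of degrees to tens of
degrees between any two integration routes: near-threshold orbit capture
has sensitive dependence (a 2° angle tolerance would demand sub-nanometre
radial agreement sustained over hundreds of orbits), so position-wise
equivalence is asserted only where capture is prompt; distribution-level
statistics are unaffected.

Fates follow the reference taxonomy: **trapped** on wall contact within the
scaffold ($0 \le z \le L$, attach-on-contact), **escaped** past the outlet,
**incomplete** at the 500 m path cap (1 mm steps, 500 000 maximum). Contact
points are located by bisection on the step, not by interpolating across it.

### The entrance-redistribution model (a deliberate deviation)

Injected particles start area-uniformly over the design's entry locus — a
centred 2 mm disk (single) or the 4 mm annulus (double). In a field with
$u_r \equiv 0$ those loci are more than 1.8 mm from the wall, and a particle
settling at 2.7 µm/s cannot cross that gap within its < 250 s transit:
the literal reduced model deposits *nothing*, at any rotation speed. The
real flow spreads the bolus across the section within an entrance length;
the reference simulations (surface injection into a 3-D entrance flow) do
the same.

The package models this kinematically: each particle's radius relaxes from
its port radius $r_0$ to a target radius $r_1$ drawn area-uniformly over the
full cross-section (coupled by area quantile, angle preserved) over an
entrance length $L_e = 2R$, with drift rate
$dr/dz = 2 s (1 - z/L_e)$, $s = (r_1 - r_0)/L_e$ — a smooth taper, because a
velocity jump at $L_e$ makes trajectories step-size sensitive. Area-uniform
(rather than flux-weighted) target radii emulate one-parcel-per-face surface
injection, which is how the reference tool counts trajectories. The two
designs thus differ in *where particles are during the entrance*: annular
entries ride close to the rotating wall precisely where the swirl is
strongest, which is the mechanism the reference text offers for the double
design's proximal deposition bias. This entrance model is a documented
sketch, not a solved entrance flow; everything downstream of $z = L_e$ is
the composite field proper.

## What the reduced model does and does not reproduce

Reproduced (all computed by the test suite, not asserted from literature):
gravitational bottom-sector deposition and a decreasing axial trend at
0 rpm with most of the bolus escaping; left/right symmetry about the
vertical plane; the double-static design deposits more proximally than the
single-rotating design at both 5 and 15 rpm; WSS means and their
rpm/flow-rate sensitivity ordering (rotation dominates flow rate); the
single design's more uniform shear profile.

Not reproduced, by diagnosable mechanism (these acceptance expectations are
deliberately left failing rather than weakened):

* *Trapped fraction rising with rotation.* With $u_r \equiv 0$, solid-body
  swirl closes the settling trajectories into epicycles of extent
  $2 v_s/\Omega$ (52 µm at 1 rpm) around displaced centres: rotation
  *suppresses* gravitational capture, and the centrifugal slip
  ($\tau_p \Omega^2 r \sim 10^{-8}$ m/s) cannot replace it. The package
  traps ~18% at 0 rpm and 1--8% under rotation (rising again from 1 to
  15 rpm); the reference reports a monotone increase, driven by 3-D
  secondary/entrance flows its geometry supports and this model excludes by
  design.
* *Circumferential uniformization at 1 rpm.* Same mechanism: at 1 rpm the
  surviving deposition is a sparse near-wall capture layer, not an
  azimuthally smeared version of the 0 rpm pattern, so its circumferential
  CV is higher, not lower.
* *Proximal bias increasing from 1 to 15 rpm.* Inverted here: the thin
  1 rpm capture layer deposits promptly where the entrance delivers it
  (proximal fraction ~0.9), while 15 rpm spiral capture strings deposits
  down the length (~0.63).
* *Axial-CV ordering between designs at 5 rpm.* The designs share the
  downstream field; their difference lives in a 13 mm entrance window and
  at 5 rpm it is smaller than replicate noise at $n = 11000$ (the 15 rpm
  ordering and the proximal-fraction orderings do hold).
* *Replicate (seed) stability at the reference's sub-1% level.* With ~2000
  trapped particles the Monte-Carlo floor on a 50-bin axial profile is
  ~9%; the suite asserts that floor (15% bound), not the full-CFD figure.

## Synthetic validation experiment

`make_punch_layout()` places 25 equally spaced 6 mm bio-punches (5 axial
stations x 5 angles) on the unrolled lumen; `synthesize_punch_counts()`
integrates the deposition density fraction over each punch footprint,
scales by total deposited cells (trapped particles x 100 cells each,
matching the represented concentration), and draws observed counts from a
negative binomial with dispersion $k$ (variance $\mu + \mu^2/k$). Clumping
from cell--cell interaction is the dominant unmodelled experimental effect,
and a two-parameter overdispersed count family is its minimal emulation;
$k = \infty$ recovers Poisson counting noise, $k \approx 5$ is the default
"visibly clumpy" setting, and `noise = "none"` returns expectations.
`compare_punch_profiles()` converts counts to punch-level density fractions
and compares axial/circumferential profiles between a map and a sample set
(synthetic or real counts in the same CSV schema) by mean absolute
difference and Spearman rank correlation. A green recovery test establishes
that 25 punches with clumping noise suffice to rank-order the simulated
axial profile ($\rho > 0.7$ at 3 replicates); it does not establish
anything about agreement with a live-cell experiment.

## Tunable parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `lumen_radius` | 6.35e-3 | m | 12.7 mm tracheal diameter |
| `flow_rate` | 2.5e-8 (1.5 mL/min) | m^3/s | recellularization flow rate |
| `rpm` | 0 (set 0/1/5/15) | rev/min | studied rotation speeds; device range 0--30 |
| `diameter` (particle) | 1e-5 | m | epithelial cell size |
| `density` (particle) | 1050 | kg/m^3 | cell density |
| `n_particles` | 11000 | — | particle-count independence threshold |
| `path_step_m`, `max_steps` | 1e-3, 5e5 | m, — | 500 m trajectory cap |
| `inlet_anchor_length`, `outlet_anchor_length` | 0.02, 0.01 | m | package parameterization (not printed for the device) |
| `inlet_port_radius`, annulus radius/half-width | 2e-3, 4e-3, 5e-4 | m | package parameterization |
| punch grid, diameter | 5 x 5, 6e-3 | —, m | 25 equally spaced 6 mm punches |
| `dispersion` k | 5 | — | clumpy counting noise; consistency checked at 0.5 and 50 |

Anchor and port dimensions are this package's parameterization of unprinted
internals; quantities sensitive to them should be read as order-of-magnitude
(the factor-1.5 acceptance bands on rotating-case WSS reflect that).

## Known limitations

No meridional secondary flow, no transient/bidirectional (peristaltic)
seeding, no two-way coupling, no cell--cell clumping during transport, no
shear-dependent attachment probability, no pressure recovery or
non-Newtonian rheology. The trapped-on-contact wall condition is the
reference's assumption, adopted here, and is optimistic at high shear.
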