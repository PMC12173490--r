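---
title: "A mesoscale E. coli swimmer: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mesoscale E. coli swimmer: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoliswim)
```

## The model

`ecoliswim` simulates a single *Escherichia coli* bacterium as a
particle-based mechanical object coupled to an explicit mesoscale solvent.
The model has four coupled components.

**Cell body.** The body surface is the superellipsoid
$(|x|/b_x)^\nu + (y/b_y)^2 + (z/b_z)^2 = 1$ with $\nu = 8.5$ (a rounded
sphero-cylinder, 3 µm long and 1 µm wide) triangulated into an elastic
network.  Edges carry worm-like-chain springs with an inverse-power
repulsion, $U = \frac{k_BT\,l_{max}}{4p}\frac{3x^2 - 2x^3}{1-x} + k_p/l$,
$x = l/l_{max}$, with extensibility $x_0 = l_0/l_{max} = 0.45$; the
repulsion coefficient of each edge is solved so the net spring force
vanishes at its rest length.  Curvature elasticity is the discrete
Helfrich energy $\frac{\kappa}{2}\sum_i \sigma_i (H_i - H_i^0)^2$ on the
cotangent dual lattice ($\sigma_{ij} = r_{ij}(\cot\theta_1 +
\cot\theta_2)/2$, $\sigma_i = \sum_j \sigma_{ij} r_{ij}/4$), with the
spontaneous curvature prescribed per vertex from the freshly triangulated
surface so that the target shape is the energy minimum.  Global area,
per-face area and enclosed volume are held by harmonic penalties; in the
driven regime the body is nearly rigid (area and volume stay within 1%).

**Flagella.** Each flagellum is a chain of $N_s$ octahedral segments: two
backbone particles shared with the neighbouring segments and four
auxiliary particles on orthogonal diameters of the mid-plane, held by 12
edge springs (rest length $r_e$) and 3 diagonal springs (rest length
$r_d$), so a 76-segment flagellum has exactly $5 N_s + 1 = 381$
particles.  Backbone bonds and auxiliary cross bonds define an
orthonormal material frame per segment; the rotation from one frame to
the next is decomposed into a twist $\phi$ about the tangent followed by
a bend $\theta$ about the normal to the two tangents, giving the strain
vector $\Omega = \theta\,n + \phi\,e^3$.  The elastic energy is
$\frac{1}{2}\sum_\alpha K_{el\alpha} \sum_n (\Omega_{n\alpha} -
\Omega_{e\alpha})^2$ with equal bending coefficients and a stiff twist
coefficient ($10^4\,k_BT$) that suppresses twisting under the motor
torque.  The equilibrium targets $\Omega_e = (0.122, -0.027, -0.217)$
per segment define a left-handed helix of radius 0.23 µm and pitch
2.56 µm with three turns over 76 segments.

**Hook, motor and excluded volume.** The first backbone particle of each
flagellum *is* a body vertex.  A hook potential $K_{hook}\sum_j
(\theta_j - \pi/2)^2$ over the anchor's ring of linked body vertices
prefers a perpendicular flagellum orientation; its stiffness is
100 $k_BT$ during runs and 500 $k_BT$ for the reverted flagellum during
tumbles (dynamic hook stiffening).  The motor applies a torque $T_m$
about the first backbone bond to the four first-segment auxiliary
particles as an exact couple (zero net force, torque exactly $T_m$ along
the axis, solved from $(\mathrm{tr}\,S\,I - S)\,\omega = M$ with $S$ the
second-moment matrix of the loaded points), and the opposite couple to
the anchor's ring, so the swimmer is force-free and torque-free to
machine precision.  Flagellum–flagellum and flagellum–body contacts use
the purely repulsive (WCA) Lennard-Jones potential.

**Fluid.** The solvent is dissipative particle dynamics:
$F^C = a(1 - r/r_c)\hat r$, $F^D = -\gamma w_R^2 (\hat r \cdot
v_{ij})\hat r$, $F^R = \sigma w_R \xi_{ij} \hat r/\sqrt{\Delta t}$ with
$w_R = (1 - r/r_c)^s$ and $\sigma^2 = 2\gamma k_BT$.  Fluid–swimmer
coupling is purely frictional ($a = 0$); there is no explicit no-slip
constraint beyond it.  All pair forces are antisymmetric, so momentum is
conserved and hydrodynamics emerges.

## Units and parameters

Internally everything is computed in raw simulation units in which the
body major half-axis is $b_x = 9$, the bundle rotation period is
$\tau = 132$, $k_BT = 1$ and the particle mass is 1.  The interface uses
the scaled units ($b_x$, $\tau$, $k_BT$); `to_SI()`/`from_SI()` map them
to metres, seconds, joules via $b_x = 1.5$ µm and $\tau = 6.7$ ms (150 Hz
bundle rotation), with $k_BT$ at 20 °C for energies and torques
(300 $k_BT \approx 1200$ pN nm).

The registry defaults (`default_config()`) are: five flagella (one polar,
four at 90° on a circumference near the rear pole, where the cross-section
reaches 95% of its maximal radius), $T_m = 300\,k_BT$ per motor, membrane
shear modulus $8.1\times10^4\,k_BT/b_x^2$, bending modulus $100\,k_BT$,
constraint coefficients $k_a = 4.05\times10^4$, $k_d = 8.1\times10^4$
($k_BT/b_x^2$), $k_v = 3.65\times10^5\,k_BT/b_x^3$; fluid
$a = 540\,k_BT/b_x$, $\gamma = 225\,\sqrt{m\,k_BT}/b_x$, $s = 0.15$,
$r_c = 0.11 b_x$ at density $2.16\times10^3\,b_x^{-3}$; coupling $a = 0$,
$\gamma = 360$, $s = 0.1$, $r_c = 0.09 b_x$; time step
$\Delta t = 2.27\times10^{-5}\tau$; run phase 18.9 τ, tumble phase
12.6 τ, polymorphic ramp 0.76 τ.

Two geometric constants are not stated self-consistently by their
sources and are fixed here once: the backbone spacing is derived from the
three-turn constraint, $\ell = 3\sqrt{(2\pi R)^2 + P^2}/76 = 0.116$ µm
(so the contour length is 8.82 µm), and the octahedron rest lengths are
$r_d = \ell$, $r_e = r_d/\sqrt 2$, the unique choice for which the
regular octahedron is exactly at spring rest length (an edge-to-diagonal
ratio of 1/2 would frustrate the scaffold).  The octahedron spring
constant ($2\times10^3\,k_BT$ per squared length unit) is a scaffold
rigidity choice: stiff enough that the octahedra stay effectively rigid,
soft enough for stable integration at the configured step.

## The polymorphic transformation and frame handedness

The two-state polymorphic transformation flips the sign of the two
bending targets $\Omega_{e1}, \Omega_{e2}$ linearly over 0.76 τ.  A
subtlety matters here: if the material frame is always completed
right-handedly ($e^2 = e^3 \times e^1$), flipping both bending components
at every junction is exactly equivalent to rotating the frame by π about
the tangent — the same physical rod, not its mirror image.  The flip
produces the opposite-handed helix only if $e^2$ carries the orientation
of the auxiliary cross bond $b^2$; under a reflection this bond makes
the frame improper, and precisely then the strain triple of the mirror
image is the sign-flipped pair with unchanged twist.  `ecoliswim`
therefore computes $e^2 = \mathrm{sign}(b^2 \cdot (e^3 \times e^1))\,
(e^3 \times e^1)$ — a piecewise-constant factor maintained by the
scaffold springs, so forces remain exact gradients — and
`build_flagellum()` selects the frame branch from the sign of
$\Omega_{e1}$, so that the sign-flipped target set builds the true
mirror helix.  During a driven simulation both helicity branches are
energy-degenerate at the flipped targets; which one the chain reaches is
decided by the dynamics, as in the physical system.

## Numerical choices

* **Forces are exact gradients.**  Bond, constraint and WCA forces are
  analytic; the bending and rod strain energies are differentiated with
  forward-mode dual numbers over the local stencil of each energy term
  (one-ring of a vertex; seven particles of a junction).  Every term is
  validated against central finite differences to better than $10^{-5}$
  relative error in the test suite, and the symplectic integrator
  conserves the energy of an isolated membrane to $10^{-4}$ of the
  excitation energy over $10^4$ steps.
* **Integrator.**  Velocity-Verlet in the DPD form: half kick, drift,
  force recomputation with half-step velocities, half kick.  The
  equilibrium kinetic temperature at the configured parameters is
  $1.001\,k_BT$.
* **Pair noise.**  The symmetric Gaussian variates $\xi_{ij} = \xi_{ji}$
  come from a counter-based hash of (seed, step, ordered pair), so runs
  are bit-reproducible and no per-pair state is stored.
* **Neighbour search.**  A linked-cell list at the largest cutoff; boxes
  smaller than three cells per dimension fall back to all-pairs.
* **Triangulation.**  Icosahedron subdivision projected radially onto the
  implicit surface, then two relaxation phases: length-weighted Laplacian
  smoothing (150 sweeps) and edge-length equalization (up to 800 sweeps)
  in which a candidate update is accepted only if the mesh stays
  outward-oriented and no triangle degenerates.  This brings the max/min
  edge ratio below 3 even for the elongated body.  Negative cotangent
  weights from obtuse angle pairs are kept — discarding them would break
  the exact partition of the surface area over the dual lattice — and a
  non-positive vertex dual area (a truly degenerate fan) aborts with a
  diagnostic.
* **Spring calibration.**  The network shear modulus is measured on a
  uniform triangular lattice under affine simple shear (exact at small
  strain for a centrosymmetric lattice, and area-preserving, so
  constraints do not contribute); both spring terms scale as $1/p$, so a
  single reference measurement fixes the persistence length.
* **Flagellum relaxation.**  L-BFGS with restarts on machine-precise
  gradients.  From the analytic zero-energy construction the residual
  force is below $10^{-9}$; from generic perturbed states the
  energy-based line search bottoms out near $10^{-5}$ (floating-point
  resolution of the energy), while the fitted helix geometry is
  converged to much better than 1%.
* **Helix fit.**  Axis from the principal component, refined together
  with a transverse offset by minimizing the radial-distance variance;
  pitch from the unwrapped phase against the axial coordinate;
  handedness from the phase slope with the axis oriented along the
  chain.
* **Degenerate cases.**  Antiparallel consecutive tangents (bend angle
  π) abort with a diagnostic rather than being regularized; overstretched
  membrane edges abort naming the edge; the small-angle limit of the
  bend axis uses a series expansion so forces stay smooth through zero
  strain.

## Desk scale versus cluster scale

The full study conditions — a domain of $8.33 \times 11.56 \times
11.56\,b_x^3$ with $2.4\times10^6$ fluid particles integrated for about
$5\times10^6$ steps — are cluster-scale and are shipped as the default
configuration (`cluster_scale = TRUE`), not exercised by the tests.  The
test fixtures use reduced systems chosen once: a $(3 b_x)^3$ box with the
fluid density reduced eightfold, flagella of 12–20 segments, body meshes
of 162–642 vertices, and a quarter time step (at the reduced density the
frictional damping of the driven flagellum is correspondingly weaker, and
the stiff scaffold springs need the smaller step for stability).  Fluid
measurements use a $(1 b_x)^3$ box with 2160 particles: temperature over
4000 steps, viscosity over 28000 steps of periodic-Poiseuille flow.  The
flagellum acceptance computations use the full $N_s = 76$ chain.

Passing the desk-scale suite establishes the structural and elastic
mechanics (geometry, exact gradients, conservation laws, force-free
actuation, phase scheduling) and the fluid thermodynamics and rheology at
small scale.  It does not establish the emergent cluster-scale
observables — bundling dynamics, swimming speed, wobbling, tumble-angle
statistics — which require the full system and are documented as
large-run validation.

## Fluid rheology

`measure_viscosity()` drives the periodic-Poiseuille flow (opposite body
forces in the two halves of the box) and fits the two parabolic branches
$v_x(z) = \frac{\rho f}{2\eta} z(w - z)$ by weighted least squares, with
a standard error from sequential blocks.  At the configured fluid
parameters the package measures $\eta \approx 7.8\times10^2\,
\sqrt{m\,k_BT}/b_x^2$ (within a few percent of the standard DPD
kinetic-theory estimate for these parameters, and consistent between
forcing amplitudes and an independent shear-wave-decay estimate), while
the registry's nominal reference viscosity is $1225.53$ in the same
units.  The acceptance suite reports the measured value and records this
discrepancy rather than adjusting any printed parameter; all SI
conversions that involve the fluid use the registry value only for the
documentary Reynolds-number bookkeeping, which is $\mathcal{O}(10^{-2})$
under either number.

## Known limitations

* The fluid does not enforce no-slip on the swimmer beyond the frictional
  coupling; the membrane is impermeable only through friction and
  excluded volume.
* The motor torque is constant — no torque–speed relationship.
* The hook is a bending-angle potential only; it has no independent
  torsional compliance.
* Only the two-state helicity model is implemented, not the full
  polymorphic landscape (normal/semicoiled/curly).
* Desk-scale runs cannot reproduce the emergent swimming observables;
  see above.
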