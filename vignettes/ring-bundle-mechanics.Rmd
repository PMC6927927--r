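---
title: "Mechanics of superelastic ring-stent bundles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of superelastic ring-stent bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ringmech` simulates the radial-support element of ring-stent grafts: a
closed ring bundle wound from multiple turns of a single superelastic
Nitinol wire, crimped into a delivery catheter and released into a
pressurized artery. This vignette documents the models, their assumptions,
the parameters that matter, and the numerical choices, in enough detail
that a reader can judge what the package's validations do and do not show.

## The bundle idealization

An *n*-turn bundle is modeled as a single beam whose section resultants
carry a turn multiplier *n*: because the turns occupy (nearly) the same
space and are tied together, they share one centerline kinematics, and a
bundle of *n* coincident wires is mathematically identical to one wire with
*n*-scaled section forces. The package asserts this equivalence to machine
precision (a model with duplicated coincident elements gives the same
solution as the multiplier). Wire-to-wire contact and the real,
suture-dependent arrangement of turns across the bundle cross section are
deliberately out of scope.

The bundle's *size* still matters for contact, so the envelope radius is
taken from circle-packing theory: the smallest circle that encloses *n*
unit circles, tabulated for *n* = 1..14 and cross-checked for *n* <= 8 by a
multi-start numerical packing optimizer (penalty descent plus a
contraction/separation polish). Contact is evaluated at the beam centerline
offset by this envelope radius.

## Superelastic wire model

Each beam section carries a grid of fibers (3 moment-matched radial rings x
8 angular stations, the outermost ring exactly on the wire surface), and
each fiber follows a one-dimensional superelastic law with linear
transformation kinetics:

* elastic response with the compliance-mixture modulus
  1/E(xi) = (1-xi)/E_A + xi/E_M below the active surface;
* forward transformation while the stress traverses [sigma_LS, sigma_LE]
  (martensite fraction xi and transformation strain grow linearly with the
  driving stress), reverse transformation on [sigma_US, sigma_UE];
* elastic unloading/reloading inside the hysteresis loop;
* compression surfaces are the tension surfaces scaled by
  sigma_CS/sigma_LS (printed onset 965 vs 636 MPa). The compression
  *unloading* surfaces are not published; reusing the same scale is an
  assumption, exposed as `compression_scale`.

Because the kinetics are linear in xi, the return mapping reduces to a
quadratic equation and is solved in closed form; the consistent tangent is
analytic. Temperature is fixed at 37 C. The model is rate independent and
non-damaging, so cyclic preconditioning settles in two to three cycles
rather than the hundred cycles used on a physical rig.

With the default 37 C parameters the austenite branch ends at
sigma_LS/E_A = 1.08% strain in tension; this single number anchors most of
the qualitative behavior (pre-strained rings sit at 0.4-0.7% strain and
reach the plateau under operational deflections; virgin rings do not).

## Beam finite element

The core is a corotational 2-node Timoshenko beam with small deformational
rotations relative to the corotated element frame: axial strain from the
chord elongation, curvature and twist from the difference of the nodal
triad rotations, mean-rotation shear (equivalent to one-point reduced
integration, locking-free). Fiber quadrature supplies the axial
force/bending moments and their tangent; torsion and transverse shear stay
elastic (austenite shear modulus, J = pi r^4/2, shear factor 0.9).

The element tangent is computed as the directional finite difference of the
element force over its own 12 dofs, *batched* across all elements in one
vectorized evaluation. This is the algorithmically consistent tangent
including every corotational geometric term and the active material branch
(step 1e-7, small enough that tangent accuracy never limits the attainable
residual of the elastic oracle problems).

The solver is incremental-iterative Newton with

* non-monotone step acceptance within a residual growth cap (slender
  beams legitimately spike the residual by orders of magnitude on the
  first Newton step of a force increment before contracting),
* an optional contact/plateau mode (`dulim` in the solver options) adding
  a displacement trust region near the element length — the radius of
  validity of the corotational linearization — and adaptive step damping
  that settles semismooth oscillation across contact and material branch
  switches, with best-state fallback,
* automatic increment bisection, and Levenberg regularization of
  near-singular tangents (a dead tip moment, for instance, passes states
  whose tangent is singular by rotational indifference of torque loading).

Welds are exact dof identifications (the crimped joint can never open).
Constraints follow the quarter-point scheme of the deployment scenario;
one additional tangential-rotation fix at a valley suppresses a genuine
zero-energy mode of a closed ring with an isotropic circular section
(uniform spin of all sections about the wire tangent changes no strain).

Oracles asserted in the test suite: cantilever tip deflection within 1% of
PL^3/3EI; a straight wire closed into a full circle by end moments with
surface strain r/R to 0.5%; pinched-ring diametral stiffness within 3% of
the thin-ring closed form; global force balance below 1e-6 N at converged
elastic states; mesh halving moves the saddle-test peak force by < 1%.

## Manufacturing pre-strain

Forming is a guided kinematic wrap: the straight wire of length pi D is
bent into a regular polygon whose per-node triad turning ramps to
2 pi / n_elem while chord lengths are preserved, so every fiber
accumulates a monotonic bending history up to +/- R_wire/R_ring exactly;
the ends are then welded and the ring released. A formed ring carries a
uniform internal bending moment and is self-equilibrated (release residual
~1e-10 N), and the finite-element peak strain reproduces the bending
closed form R_wire/R_ring to ~1e-10 relative — the forming validation is
exact by construction of the wrap, and the release solve confirms the
discrete state is an equilibrium. For the four fixture rings these strains
are 0.42-0.67 x 10^-2. The no-pre-strain variant creates the circle
directly with virgin fibers (zero stored energy).

## Saddle pull test

Four axial-spring "strings" (stiffness 7.41 N/mm per 100 mm of length,
scaled inversely with the actual length) connect the quarter points to two
crosshead reference points on the ring axis, 100 mm above and below the
ring plane by default (the rig geometry is not dimensioned in print; the
symmetric pyramidal arrangement is the package's documented choice). The
crossheads are driven apart to an extreme and then cycled between
positions derived from the saddle amplitudes at 30% and 10% oversize
(arc-length conservation of the inextensible ring on the implied vessel
cylinder; the crosshead displacement bound is twice the amplitude). The
extreme pull uses a 50% overshoot over the 30% position so the wire enters
the transformation plateau, as the physical preconditioning (which
emulates compaction strains) does. Strings carry no compression; slack is
flagged. Rotation about the wire tangent is fixed at the four tie points,
with tangential in-plane fixes for stability.

The experimental force-displacement curves are not published numerically,
so no quantitative deviation can be recomputed; the suite asserts the
directional result instead: removing the manufacturing pre-strain makes
the response stiffer at every displacement of the cycling region for all
four rings, because the virgin wire stays below the 1.08% austenite limit
and never reaches the plateau.

## Artery tube

The vessel is a 6th-order reduced-polynomial hyperelastic tube
(coefficients c1..c6 in MPa, only the first volumetric term present;
implied small-strain Poisson ratio > 0.4999). Its pressure-radius response
is computed semi-analytically: incompressible plane-strain thick-wall
inflation, integrated through the 2 mm wall by Gauss quadrature and
root-found for the inner radius (tolerance 1e-6 mm). Sizing picks the
unloaded radius so that the radius at the time-weighted mean pressure
P_m = P_d + (P_s - P_d)/3 = 93.3 mmHg gives the requested ring oversize.

The ring couples to the tube through an effective radial stiffness: the
total radial contact force, spread over an axial footprint
L_eff = 1.5 sqrt(R t) (the bending decay length scale of a pressurized
cylindrical shell under a ring line load), acts as an equivalent extra
luminal pressure and the inflation is re-solved; a secant iteration closes
the coupling to 1e-3 mm. The vessel therefore remains a cylinder of
varying radius — the single largest fidelity reduction in the package, made
deliberately to keep the constitutive content (the published
pressure-radius behavior) at desk scale. Local indentation of the wall by
the wire is folded into the contact penalty, whose default (2 N/mm per
node) is the indentation stiffness of the 2 mm wall under a one-element
wire segment at the physiologic tangent modulus (0.3-1 MPa). The rigid
delivery-system surfaces use a stiff penalty (50 N/mm).

## Compaction and deployment

Crimping a ring whose diameter is 4-7x the catheter bore is the hardest
step. Under a perfectly axisymmetric squeeze the flat ring remains an
*exact but unstable* equilibrium at every sheath radius, and the folded
branch passes through snap-throughs that defeat equilibrium
path-following at practical increment counts. The package therefore drives
the shrink as a displacement-guided kinematic program along an
inextensible fold family on the current sheath cylinder:

    z(phi) = (h/2) (1 - tanh(w cos 2 phi)/tanh(w)),

which is the shallow sinusoidal saddle for small w and hairpin legs with
rounded turns for large w. At each radius the amplitude h follows from
arc-length conservation and the sharpness w is chosen to minimize the peak
curvature; nodes are placed at *chord* spacing (arc spacing would compress
high-curvature elements axially) and material frames are transported
torsion-free. The fiber states are committed at every increment, so the
full monotonic bending history — the point of simulating compaction at all
— is retained; at the catheter radius the turns carry 4-12% transient
strain and transform fully (xi = 1) at the hairpins. A seeded smooth
low-harmonic jitter of the guided arc positions breaks residual symmetry
deterministically.

Deployment retraces the family as the sheath re-inflates, until the ring
is just inside the pressurized vessel; from there the equilibrium solver
takes over (curvatures are back in the range the mesh resolves): pin
springs to the guided positions are ramped out, the ring lands on the
vessel contact, and the wall radius is converged against the contact load
at P_m, then cycled P_d -> P_s for two cycles (the rate-independent loop
settles by the second cycle; a third changes strain extrema by < 0.5%).
Outputs: chronic outward force (sum of radial nodal contact forces on the
wall) reported at P_m (the extraction pressure is not stated in print;
diastolic and systolic values are also emitted), peak surface strains at
diastole and systole (evaluated at the exact section-boundary extreme
eps_c +/- r |kappa|, not at fiber sample points), and the maximum
cycle-mean strain M_eps = max over elements of the mean of the two phase
extrema.

Known limitation: with the default conditions the four fixture rings give
peak deployed strains of about 1.23, 0.86, 1.00 and 0.74% — three inside
the expected 0.7-1% operational band, while the thinnest-wire ring (ring
1) overshoots by ~20%. This traces to the cylindrical-vessel
idealization: a three-dimensional wall bulges locally under the saddle
legs and relieves peak curvature in a way the axisymmetric radius coupling
cannot. The overshoot is reported as-is rather than absorbed into a
contact parameter.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| fiber grid | 3 x 8 | - | exact area/I/4th moment; surface sampled |
| force tolerance (oracles) | 1e-7 | N | elastic problems converge tightly |
| force tolerance (vessel-coupled) | 0.01 | N | ~0.5% of COF; friction regularization floor |
| contact smoothing depth d0 | 0.02 | mm | C1 penalty, stops active-set chatter |
| vessel penalty | 2 | N/mm | wall indentation stiffness under a wire segment |
| sheath penalty | 50 | N/mm | rigid polymer surfaces |
| friction (vessel / sheath) | 0.05 / 0 | - | published contact treatment |
| catheter bore | 6.9 | mm | ~20.7 Fr delivery profile (not dimensioned in print) |
| inner tube | 2 | mm | delivery core (not dimensioned in print) |
| L_eff | 1.5 sqrt(Rt) | mm | shell bending decay length |
| fold jitter | 1e-4 D_ring | mm | seeded, smooth, deterministic |
| pulse cycles | 2 | - | rate-independent loop closure |

Problem sizes used by the shipped validations: 96 elements per ring (64
and 48 for test-scale runs), 50 compaction increments, 30 unfold
increments. Halving the element size changes the saddle peak force by
less than 1% within the operational deflection range, and moving from 64
to 96 elements changes deployed strain extrema by about 1%. One caveat:
when the pull is driven deep into the transformation plateau, the
transformation front localizes element by element (the plateau tangent is
two orders softer than the elastic branches) and forces downstream of the
extreme converge only to about 2% in the mesh — a known property of
plateau materials without gradient regularization, not a discretization
defect of the elastic response.

## What the validations do and do not show

Everything here runs on synthetic geometry built from the four printed
ring configurations; no measured force-displacement or strain data are
available in machine-readable form. Passing tests therefore demonstrate:
internal consistency of the constitutive model (loop closure, dissipation,
rate independence), convergence of the beam core to classical closed
forms, exact reproduction of the printed packing/geometry/material/
pressure constants, the analytical forming-strain validation, and the
*direction* of the manufacturing-strain effect on structural stiffness.
They do not certify absolute agreement with bench force measurements
(the published deviations 0-7% cannot be recomputed without the
experimental curves, and the un-dimensioned rig geometry enters the
comparison), and the deployed strain band check inherits the
cylindrical-vessel idealization discussed above.
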