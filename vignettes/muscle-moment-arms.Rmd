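---
title: "Muscle wrapping, constraining sheets, and moment-arm decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle wrapping, constraining sheets, and moment-arm decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclewrap)
```

## The problem

A muscle's capacity to rotate a joint is summarized by its *moment arm*: the
shortest perpendicular distance between the muscle's line of action and the
joint's centre (or axis) of rotation. Multiplied by muscle force, it gives
joint torque. Computing moment arms dynamically — per frame of a measured
motion, on subject-specific bone geometry — requires (i) a muscle path that
respects the bones (wrapping), (ii) the point where the muscle last touches
the distal bone (the *departure point*) and the direction of pull there, and
(iii) a decomposition of the resulting moment arm about anatomically
meaningful axes (elevation, plane of elevation, axial rotation for the
glenohumeral joint).

`musclewrap` implements this pipeline for triangle-mesh bone geometry (STL)
and plain-text rigid-body kinematics, together with a programmatic
verification model of known geometry — a 30 mm sphere on a stick rotating
against a rectangular prism — whose every quantity has a closed-form
tangent-geometry oracle.

## Muscle-line wrapping

A muscle line is a polyline of `n_segments + 1` nodes (default 100 segments,
which resolves departure-point motion to well under a millimetre at
glenohumeral scale) with its first and last node pinned at the origin and
insertion. The solver repeats two steps until stationary:

1. move every interior node toward the average of its two neighbours
   (uniform weights; the node itself is excluded), and
2. if the node then penetrates an obstacle, project it back onto the
   obstacle's surface, offset outward by `line_radius_mm` along the local
   normal (`line_radius_mm = 0` puts the line directly on the bone).

The fixed point has every interior node either at its neighbours' average
(straight, free spans) or on an obstacle's offset surface (contact spans) —
a discrete geodesic: tangent segments joined by on-surface arcs, the
shortest path in its homotopy class. Convergence is declared when the
largest per-sweep node displacement falls below `convergence_tol_mm`
(default 1e-4 mm; the path length is stationary at the optimum, so residual
transverse error of this size perturbs lengths only at second order). Nodes
are updated sequentially (Gauss–Seidel ordering) and the averaging step can
be over-relaxed (`relaxation`, default 1.6), which changes the iteration
count, not the fixed point; with identical inputs the solver is bitwise
deterministic.

Penetration is decided by signed distance: the nearest surface feature
(face, edge or vertex) is found through a uniform spatial grid and the sign
comes from its angle-weighted pseudo-normal, which is exact for closed
meshes and gives a consistent orientation for open ones. With several
obstacles, a node is projected onto the most-penetrated body first and
re-tested (at most five sub-iterations), a deterministic rule for the rare
multi-body contacts.

Contact classification labels each node with the nearest body whose offset
signed distance is at most `contact_tol_mm` (default 0.1 mm — above the
projection residual, far below anatomic scales); ties within 1e-12 mm go to
the lexicographically first body name and are logged. The departure point is
the highest-index node in contact with the target (distal) body, and the
line of action is the unit vector along the segment leaving it toward the
origin — the direction the muscle pulls on that bone.

## Moment arms

The departure point is first *refined* to the foot of the perpendicular from
the centre of rotation onto the line of action,
`p' = p + ((c - p)·u) u`, which removes the along-line quantization of the
discrete departure node. The resultant moment arm is then
`|(p' - c) × u| = |p' - c|`. Components about an axis `a` are
`((p' - c) × u) · a`, evaluated for the scapular anterior axis
(glenohumeral elevation; reported sign-flipped so elevation is positive),
the scapular superior axis (plane of elevation), and the humeral shaft axis
re-posed per frame (axial rotation). Because `(p' - c) × u` changes only at
second order when the line of action tilts about its own direction, the
resultant is insensitive to the dominant discretization errors; the
decomposed components inherit a first-order sensitivity, which is why they
carry a larger verification tolerance.

Anatomic frames are built from landmark probes: the scapular frame from the
trigonum spinae, inferior angle, and glenoid (or glenosphere) centre, the
last of which serves as origin — lateral axis toward the glenoid, anterior
axis normal to the landmark plane, superior axis completing the
right-handed triad, with the superior direction disambiguated away from the
inferior angle (a reflected, left-sided landmark set is flipped and
logged). The humeral shaft axis comes from a least-squares cylinder fit
(radius profiled out, axis initialized from the principal direction of
greatest extent), oriented toward the head centre, with the lesser
tuberosity clocking the anterior axis.

Per-frame records carry length, resultant and decomposed moment arms, the
departure point and unit vector, and flag tokens; frames whose departure
point jumps by more than `jump_tol_mm` (default 5 mm, far above the
sub-millimetre per-frame motion of a smooth solution at 1-degree steps) are
flagged `departure_jump`.

## The constraining sheet

A freely wrapped line follows the globally shortest path, which on a convex
head at large rotations slides far from the muscle's anatomic track —
visible in the verification model as lateral lines splaying toward the
equator of the sphere. The constraining sheet counters this: a thin
deformable strip lofted between origin and insertion that guides the lines.

The sheet is lofted from five lane curves of fifty subdivisions each —
geodesic curves on the bone in the anatomic workflow (`geodesic_curve`:
Dijkstra over the mesh edge graph, straightened by on-surface smoothing,
then resampled at uniform arc length; exact-geodesic algorithms would gain
nothing at the tolerances involved), or reference-frame wrap curves in the
verification scene — into a structured 5 x 51 grid of 400 triangles. Its
mechanics are deliberately simple: the material is a numerical device whose
only job is to be a compliant, penetration-free surface, so the membrane is
discretized as edge springs (structural along and across the lanes, shear
diagonals at half weight) with stiffness `E · t · w / l0` per edge (Young's
modulus `E` = 1 MPa, thickness `t` = 1 mm, tributary width `w`), a Poisson
ratio of zero matching the uncoupled springs, and a quadratic penalty on
penetration with stiffness 100 x the mean spring stiffness. Pre-tension —
used to pull slack out of the strip and suppress buckling in regions of
high curvature — is realized by scaling all rest lengths by
`pretension_scale` (default 0.95) rather than by a separate shrink-then-pull
solve step; the steady state is the same.

Equilibrium is found per frame by minimizing the total energy with
Newton-type steps: the search direction solves the sparse system assembled
from the exact spring Hessian blocks (transverse curvature clamped at zero
to keep the system positive semi-definite) plus the contact Hessian on
currently penetrating nodes, damped by a backtracking line search so the
stored energy trace is non-increasing, with steps capped at 10 mm. On a
cold start the contact penalty is ramped over five load steps; successive
frames warm-start from the previous solution and typically converge in
about ten iterations. Marching frame by frame and jumping directly to a
frame agree to below 1e-6 mm, so the per-frame solutions are genuine
equilibria, not path artifacts.

Muscle lines are coupled to the sheet *materially*: each node of the
reference-frame wrap is projected once onto the rest sheet (closest point,
stored as barycentric coordinates) and thereafter evaluated on the deformed
sheet, so the line follows the sheet's motion. Re-projecting onto the
deformed sheet every frame would let nodes migrate across the sheet toward
whatever happens to be closest and defeat the purpose of the constraint.
Contact states and the departure point are re-derived on the constrained
line each frame. Buckling — the known failure mode of thin sheets under
large deformation — is detected per frame as triangles whose normal opposes
the area-weighted normal field of their neighbours, plus self-intersecting
triangle pairs, and propagates as a `buckling` flag on the affected records.

## The verification model

`build_validation_scene()` constructs the verification scene
programmatically: a 30 mm-radius icosphere (subdivision 5; maximal chordal
deviation from the sphere about 0.006 mm) on a 6 mm stick as the "humerus",
a rectangular prism as the "scapula", three muscle lines (superior,
bisector, inferior) from the prism face to insertions fixed to the humerus,
and external rotation of 0–90 degrees about the stick axis in 1-degree
Rodrigues increments (91 frames; the step is configurable, and halving it
moves the summary statistics by well under 0.05 mm).

The line endpoints are a package choice, derived from tangent geometry
before any solver ran, under four constraints: every line's straight chord
must penetrate the sphere at every frame (the scene builder refuses
otherwise); wrapped contact arcs must stay below 180 degrees, where the
wrap is a stable local minimum; the free wrap of the lateral lines must
splay visibly at end range; and the lane-plane model must predict
unconstrained-vs-constrained length differences within the verification
bounds. Origins sit at (-35, y0, 0) mm with y0 = +7.5, 0, -7.5 (superior /
bisector / inferior), insertions 34 mm from the stick axis at an initial
azimuth of 110 degrees, same lane offsets. Wider lane offsets (e.g.
+/-15 mm) make the free-wrap geometry so oblique that no choice of
endpoints keeps the length differences inside the verification bounds while
chords penetrate at all frames — a useful reminder that the splaying
pathology grows quickly with obliquity. The scene's sheet uses no
pre-tension (`pretension_scale = 1`): the convex sphere cannot buckle the
strip, and pre-shrinking would pull the lateral lanes toward the equator
and bias the decomposed components for no benefit.

Every quantity in this scene has a closed-form expectation from tangent
geometry in a plane: the free wrap lies in the plane of origin, insertion
and sphere centre (`sphere_wrap_analytic`), and the physiologic,
sheet-guided path lies in its lane plane at offset y0, wrapping the circle
of radius sqrt(30^2 - y0^2) (`circle_wrap`). Departure point, line of
action, length and all decomposed components follow in closed form, so the
verification run compares its computed records against an oracle that never
touches a mesh or an iteration.

`run_validation()` executes the full experiment in both modes and
summarizes: the maximal deviation of the resultant moment arm from the
sphere radius; the maximal decomposed-component error of the constrained
lines and the bisector against the lane-plane expectation; the maximal
length difference between modes; and the corresponding unconstrained
lateral error, which exceeds the constrained one by more than an order of
magnitude while the resultants stay on the radius — the signature of
non-physiologic splaying that motivates the sheet.

What the verification scene does *not* emulate: real bone meshes are
non-convex and rough, kinematics are noisy and non-axial, origins and
insertions are areas rather than points, and muscle paths interact with
soft tissue that no sheet represents. Passing these checks shows the
machinery is correct at tight tolerances on known geometry; it does not
certify accuracy on anatomic data, which the authors of any study must
assess per application (mixed constrained/unconstrained line choices
included — the package exposes the constraint mode per line and does not
auto-select it).

## Numerical choices and limitations

- Problem sizes: the default verification run solves 3 lines x 91 frames x
  2 modes at 100 segments plus 91 sheet equilibria of 255 nodes; it
  completes in about two minutes on one CPU.
- Tendon excursion (the identity "axial moment arm = -dL/dtheta") holds to
  0.8 % for wrapped lines at 1-degree central differences. For
  sheet-constrained lines the lane length inherits a ~0.03 mm facet wobble
  from the 50-subdivision sheet, which 1-degree differentiation amplifies to
  a few percent at isolated frames; at 100 subdivisions the identity holds
  below 2 % everywhere. The sheet resolution is kept at 50 subdivisions in
  the reference construction, and the finer sheet is used where that
  identity itself is under test.
- The membrane replaces a nonlinear finite-element solve. Bit-compatibility
  with any particular FE package is not claimed and not needed: the
  verification bounds are tolerance-based, and the sheet's stress state is
  explicitly out of scope (only its shape matters).
- STL is read in both ASCII and binary dialects with 1e-6 mm vertex
  welding; the kinematics text dialect (16 numbers per row, row-major 4x4,
  optional leading timestamp detected from a 17th column) is a package
  convention, since upstream tools specify only "a text file". Rotation
  blocks within 1e-3 of orthonormal are repaired by polar decomposition;
  anything worse is rejected.
- Muscle force, length–tension scaling and joint torques are out of scope;
  the package reports geometry (lengths, moment arms) only.
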