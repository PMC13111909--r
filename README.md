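# musclewrap

Dynamic muscle lengths and moment arms of musculoskeletal joints from
triangle-mesh bone geometry and rigid-body kinematics.

A muscle's **moment arm** about a joint is the shortest perpendicular
distance between its line of action and the joint's centre of rotation; it
converts muscle force into joint torque and quantifies the muscle's role in
each plane of motion. `musclewrap` computes, per frame of a measured motion:

- the muscle path, by **obstacle-respecting wrapping**: the path is
  discretized into segments (101 nodes by default) and relaxed — each
  interior node migrates toward the average of its neighbours and is
  projected back onto the bone surface when it penetrates — until the
  locally shortest, penetration-free polyline is reached;
- an optional **constraining sheet**: a thin membrane strip lofted from
  geodesic lane curves (5 lanes x 50 subdivisions), relaxed to quasi-static
  equilibrium with penalty contact against the bones, onto which muscle
  lines are materially bound when free wrapping takes non-physiologic
  shortcuts;
- the **departure point** (last node contacting the distal bone) and the
  line-of-action unit vector `u` there, refined to the foot of the
  perpendicular from the centre of rotation `c`, giving the resultant
  moment arm `|(p - c) x u|` and its components about the anatomic axes —
  scapular anterior axis (elevation, sign-flipped for reporting), scapular
  superior axis (plane of elevation) and the cylinder-fit humeral shaft
  axis (axial rotation).

Inputs are STL meshes (ASCII or binary), plain-text per-frame 4x4 rigid
transforms, and a YAML scene configuration naming probes (landmarks, muscle
origins/insertions) attached to bodies. Results are a fixed-schema CSV
(`frame, time_s, muscle, length_mm, moment_arm_mm, ma_elevation_mm,
ma_plane_mm, ma_axial_mm, departure_x/y/z, uvec_x/y/z, flags`). All lengths
are millimetres.

## Worked example

Wrap a muscle line around a 30 mm sphere (the humeral-head stand-in of the
verification model) and measure its moment arm about the sphere centre:

```r
library(musclewrap)
sphere <- mesh_icosphere(radius = 30, subdivisions = 5, body_name = "humerus")
origin <- c(-35, 0, 0)                      # medial, on the scapula side
insertion <- c(34 * cos(20 * pi/180), 0, 34 * sin(20 * pi/180))
line <- wrap_line(origin, insertion, list(sphere), wrap_params(), name = "bisector")
line <- find_departure(line, "humerus")
print(line)
#> muscle_line 'bisector': 100 segments, length 86.860 mm, 66 contact nodes

cor <- c(0, 0, 0)                           # sphere centre = centre of rotation
p <- refine_departure(line$departure_point, line$departure_uvec, cor)
resultant_moment_arm(p, line$departure_uvec, cor)
#> [1] 29.99253
sphere_wrap_analytic(origin, insertion, cor, 30)$length
#> [1] 86.87185
```

The wrapped length (86.860 mm) agrees with the closed-form
tangent-plus-arc path (86.872 mm) to ~0.01 mm, and the measured moment arm
recovers the sphere radius to 0.007 mm — a line tangent to a sphere always
acts at one radius from its centre, which is what makes this scene a
verification oracle.

The full verification experiment (sphere-on-stick vs prism, three
subscapularis-like lines, 0–90 degrees of external rotation in 1-degree
steps, free and sheet-constrained modes) runs in about two minutes:

```r
res <- run_validation()
str(res$summary[2:5])
#> $ max_ma_deviation                 : num 0.0189
#> $ max_constrained_component_error  : num 0.478
#> $ max_unconstrained_component_error: num 17.2
#> $ max_length_difference            : num 3.66
```

Resultant moment arms stay within 0.019 mm of the sphere radius in both
modes; sheet-constrained decomposed components match the analytic
tangent-geometry expectation within 0.48 mm; and the free lateral lines —
which visibly splay toward the sphere's equator at end range — show
decomposed errors of up to 17.2 mm (36x the constrained error) even though
their resultant moment arm stays on the radius. That contrast is the reason
the constraining sheet exists.

## Command line

```sh
inst/cli/musclewrap run --config scene.yaml --out results/ [--frames 0:90]
inst/cli/musclewrap validate [--spec overrides.yaml] [--out results/]
inst/cli/musclewrap sheet-debug --out results/     # exports deformed sheets as STL
```

`validate` prints the three verification deltas with pass/fail against the
0.3 / 0.7 / 5.9 mm bounds and exits non-zero on failure.

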