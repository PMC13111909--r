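Package: musclewrap
Title: Dynamic Muscle Lengths and Moment Arms from Wrapped Muscle Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies dynamic muscle lengths and moment arms of
    musculoskeletal joints from triangle-mesh bone geometry and rigid-body
    kinematics. Muscle paths are computed with an obstacle-respecting
    wrapping algorithm (iterative neighbour averaging with projection back
    onto the bone surface), optionally guided by a deformable constraining
    sheet lofted from geodesic curves and relaxed as a quasi-static
    edge-spring membrane with penalty contact. Resultant moment arms are
    evaluated at the departure point of each line and decomposed about
    anatomic coordinate axes (ISB-style scapular frame, cylinder-fit humeral
    shaft axis). Includes STL and plain-text kinematics I/O, a programmatic
    sphere-on-stick verification model with closed-form tangent-geometry
    oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
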