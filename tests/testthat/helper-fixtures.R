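# Shared fixtures: small meshes, an ASCII cube STL, and cached heavy runs.

# unit cube as ASCII STL text (12 facets, duplicated vertices per facet)
cube_stl_text <- function() {
  v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  quads <- list(
    c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
    c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6)
  )
  out <- c("solid cube")
  for (q in quads) {
    for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
      out <- c(out, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %g %g %g", v[tri, 1], v[tri, 2], v[tri, 3]),
               "    endloop", "  endfacet")
    }
  }
  c(out, "endsolid cube")
}

# flat rectangular grid mesh in the z = 0 plane
flat_grid_mesh <- function(nx = 11, ny = 5, dx = 1, dy = 1) {
  gr <- expand.grid(x = seq(0, (nx - 1) * dx, dx), y = seq(0, (ny - 1) * dy, dy))
  v <- cbind(gr$x, gr$y, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  trimesh(v, f, "flat")
}

rigid_transform_random <- function() {
  ax <- rnorm(3)
  rodrigues(ax / sqrt(sum(ax^2)), runif(1, 0, 2 * pi), rnorm(3, sd = 20))
}

# cached heavy runs, shared across test files
.mw_test_cache <- new.env(parent = emptyenv())

full_validation_run <- function() {
  if (is.null(.mw_test_cache$full)) {
    .mw_test_cache$full <- run_validation()
  }
  .mw_test_cache$full
}

fine_sheet_constrained_run <- function() {
  if (is.null(.mw_test_cache$fine)) {
    .mw_test_cache$fine <- run_validation(
      validation_spec(sheet_subdivisions = 150), modes = "constrained"
    )
  }
  .mw_test_cache$fine
}

# a small sheet draped over a 30 mm sphere with pinned end columns
sphere_draped_sheet <- function(pretension_scale = 0.95) {
  sph <- mesh_icosphere(30, c(0, 0, 0), 3, "ball")
  curves <- lapply(seq(-6, 6, length.out = 5), function(y0) {
    wrap_line(c(-45, y0, 5), c(45, y0, 5), list(sph),
              wrap_params(n_segments = 40), name = "lane")$nodes
  })
  sheet <- loft_sheet(curves, attach = list(start = "left", end = "right"),
                      pretension_scale = pretension_scale)
  relax_sheet(sheet, list(sph))
}

# scene configuration files for the ingestion tests (synthetic stand-ins for
# externally supplied patient meshes and kinematics)
write_synthetic_scene_config <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ball <- mesh_icosphere(20, c(0, 0, 0), 3, "ball")
  blade <- mesh_box(c(-45, 0, 0), c(10, 40, 30), "blade")
  write_stl(ball, file.path(dir, "ball.stl"))
  write_stl(blade, file.path(dir, "blade.stl"))
  n <- 11
  ang <- seq(0, 50, length.out = n) * pi / 180
  mo <- rigid_motion("ball", lapply(ang, function(a) rodrigues(c(0, 1, 0), a)),
                     timestamps = seq(0, 1, length.out = n))
  write_kinematics(mo, file.path(dir, "ball.txt"))
  yaml::write_yaml(list(
    bodies = list(
      ball = list(stl = "ball.stl", kinematics = "ball.txt"),
      blade = list(stl = "blade.stl")
    ),
    probes = list(
      orig = list(body = "blade", position = c(-39, 0, 0)),
      ins = list(body = "ball", position = c(-5, 0, 23)),
      cor = list(body = "ball", position = c(0, 0, 0)),
      ts = list(body = "blade", position = c(-50, 0, 0)),
      ia = list(body = "blade", position = c(-50, -15, 0)),
      gc = list(body = "blade", position = c(-39, 0, 0)),
      lt = list(body = "ball", position = c(5, 5, 19)),
      shaft_top = list(body = "ball", position = c(0, -5, 0)),
      shaft_bot = list(body = "ball", position = c(0, -30, 0))
    ),
    muscles = list(
      wrapper = list(origin = "orig", insertion = "ins",
                     obstacles = list("ball"), constraint = "unconstrained")
    ),
    landmarks = list(
      trigonum = "ts", inferior_angle = "ia", glenoid_center = "gc",
      center_of_rotation = "cor", lesser_tuberosity = "lt",
      shaft_axis = list("shaft_top", "shaft_bot")
    )
  ), file.path(dir, "scene.yaml"))
  file.path(dir, "scene.yaml")
}
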