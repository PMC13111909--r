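test_that("geodesic curves: straight on a plane, great-circle on a sphere", {
  flat <- flat_grid_mesh()
  g <- geodesic_curve(flat, c(0.5, 0.5, 0), c(9.5, 3.5, 0), 20)
  expect_equal(nrow(g), 21L)
  expect_equal(sum(sqrt(rowSums(diff(g)^2))), sqrt(9^2 + 3^2), tolerance = 1e-6)

  sph <- mesh_icosphere(30, c(0, 0, 0), 4, "ball")
  th <- 1.2
  g2 <- geodesic_curve(sph, c(30, 0, 0), 30 * c(cos(th), sin(th), 0), 50)
  len <- sum(sqrt(rowSums(diff(g2)^2)))
  expect_lt(abs(len - 30 * th) / (30 * th), 0.02)

  expect_warning(g3 <- geodesic_curve(sph, c(30, 0, 0), c(30, 0, 0), 50),
                 "degenerate")
  expect_equal(nrow(g3), 1L)
  expect_error(geodesic_curve(sph, c(40, 0, 0), c(30, 0, 0), 10, surface_tol = 0.5),
               "off the surface")
})

test_that("lofting builds the structured strip with its attachments", {
  curves <- lapply(seq(0, 4, 1), function(y) cbind(seq(0, 10, length.out = 51), y, 0))
  sh <- loft_sheet(curves, attach = list(start = "a", end = "b"),
                   pretension_scale = 1)
  expect_equal(nrow(sh$rest_mesh$faces), 400L)  # 2 * 4 * 50 triangles
  expect_equal(mesh_area(sh$rest_mesh), 40, tolerance = 1e-9)
  expect_equal(nrow(sh$boundary_attachments), 10L)
  expect_setequal(unique(sh$boundary_attachments$body), c("a", "b"))

  # curves on a sphere loft to vertices on the sphere
  sph <- mesh_icosphere(30, c(0, 0, 0), 4, "ball")
  sc <- lapply(seq(-0.3, 0.3, length.out = 5), function(el) {
    t(vapply(seq(0, 1, length.out = 26), function(s) {
      30 * c(cos(el) * cos(s * 1.5), sin(el), cos(el) * sin(s * 1.5))
    }, numeric(3)))
  })
  sh2 <- loft_sheet(sc)
  expect_lt(max(abs(sqrt(rowSums(sh2$rest_mesh$vertices^2)) - 30)), 1e-9)

  expect_error(loft_sheet(list(curves[[1]], curves[[2]][1:30, ])), "mismatched")
  expect_error(sheet_material(poisson_ratio = 0.3), "poisson_ratio = 0")
})

test_that("relaxation keeps a planar sheet planar and the energy monotone", {
  curves <- lapply(seq(0, 4, 1), function(y) cbind(seq(0, 10, length.out = 26), y, 0))
  sh <- loft_sheet(curves, attach = list(start = "a", end = "b"),
                   pretension_scale = 1)
  sh <- relax_sheet(sh, list())
  expect_lt(max(abs(sh$deformed[, 3])), 1e-3)
  expect_true(all(diff(sh$energy_trace) <= 0))
  expect_false("unconverged" %in% sh$flags)
})

test_that("a sheet draped over a 30 mm sphere respects the contact bound", {
  sh <- sphere_draped_sheet()
  expect_lt(sh$max_penetration, 0.3)
  r <- sqrt(rowSums(sh$deformed^2))
  expect_true(all(r >= 30 - 0.3))
  expect_true(any(r < 30.5))             # it actually touches the sphere
  expect_true(all(diff(sh$energy_trace) <= 0))
  expect_length(detect_buckling(sh), 0L) # smooth convex drape cannot fold
})

test_that("pre-tension pulls slack out of the lanes", {
  # wavy lanes between pinned end columns: with pre-tension the relaxed lanes
  # are shorter (tauter) than without
  mk <- function(pt) {
    curves <- lapply(seq(0, 4, 1), function(y) {
      s <- seq(0, 10, length.out = 26)
      cbind(s, y, 0.8 * sin(s * pi / 2.5))
    })
    sh <- loft_sheet(curves, attach = list(start = "a", end = "b"),
                     pretension_scale = pt)
    relax_sheet(sh, list(), params = sheet_solver_params(max_iterations = 3000))
  }
  lane_len <- function(sh) {
    v <- sh$deformed[seq(3, nrow(sh$deformed), by = sh$n_lanes), ]
    sum(sqrt(rowSums(diff(v)^2)))
  }
  expect_lt(lane_len(mk(0.9)), lane_len(mk(1)))
})

test_that("muscle lines bound to the sheet follow its motion exactly", {
  sh <- sphere_draped_sheet()
  # a line that already lies on the sheet is unchanged by the constraint
  rows <- seq(3, nrow(sh$rest_mesh$vertices), by = sh$n_lanes)
  ln <- musclewrap:::new_muscle_line("on_sheet", sh$rest_mesh$vertices[rows, ],
                                     wrap_params(n_segments = length(rows) - 1))
  binding <- bind_line_to_sheet(ln, sh)
  undeformed <- sh
  undeformed$deformed <- undeformed$rest_mesh$vertices
  same <- constrain_line_to_sheet(ln, undeformed, binding = binding)
  expect_equal(same$nodes, ln$nodes, tolerance = 1e-9)

  # after constraining, every node lies on the deformed sheet surface
  con <- constrain_line_to_sheet(ln, sh, binding = binding)
  dist <- abs(mesh_query(sheet_as_trimesh(sh), con$nodes)$sdist)
  expect_lt(max(dist), 1e-9)
})

test_that("folded and self-intersecting triangles are flagged", {
  flat <- flat_grid_mesh(4, 3)
  expect_length(detect_buckling(flat), 0L)

  # two consistently wound triangles, the second folded back over the first
  fold <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.9, 0.5, 0.05)),
                  rbind(c(1, 2, 3), c(1, 3, 4)), "fold")
  expect_setequal(as.integer(detect_buckling(fold)), c(1L, 2L))

  # an edge piercing a vertex-disjoint triangle
  pierce <- trimesh(
    rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
          c(0.5, 0.5, -1), c(0.7, 0.5, 1), c(3, 3, 1)),
    rbind(c(1, 2, 3), c(4, 5, 6)), "pierce"
  )
  flagged <- detect_buckling(pierce)
  expect_true(all(c(1L, 2L) %in% attr(flagged, "self_intersecting")))
})
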