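test_that("the scapular frame matches its landmark construction and is equivariant", {
  cs <- build_scapular_cs(c(-100, 0, 0), c(-80, -120, 0), c(0, 0, 0))
  expect_equal(cs$origin, c(0, 0, 0))
  expect_equal(cs$z_axis, c(1, 0, 0))
  expect_equal(cs$x_axis, c(0, 0, -1))
  expect_equal(cs$y_axis, c(0, 1, 0))
  # right-handedness is part of the constructor contract
  expect_equal(musclewrap:::cross3(cs$x_axis, cs$y_axis), cs$z_axis,
               tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:10) {
    T <- rigid_transform_random()
    tp <- function(p) drop(musclewrap:::apply_transform(T, p))
    cs2 <- build_scapular_cs(tp(c(-100, 0, 0)), tp(c(-80, -120, 0)), tp(c(0, 0, 0)))
    R <- T[1:3, 1:3]
    expect_equal(cs2$x_axis, drop(R %*% cs$x_axis), tolerance = 1e-9)
    expect_equal(cs2$y_axis, drop(R %*% cs$y_axis), tolerance = 1e-9)
    expect_equal(cs2$z_axis, drop(R %*% cs$z_axis), tolerance = 1e-9)
  }

  expect_error(build_scapular_cs(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0)), "collinear")
  # handedness guard: even a mirrored landmark set yields a right-handed
  # frame with the superior axis pointing away from the inferior angle
  csm <- build_scapular_cs(c(-100, 0, 0), c(-80, 120, 0), c(0, 0, 0))
  expect_equal(musclewrap:::cross3(csm$x_axis, csm$y_axis), csm$z_axis,
               tolerance = 1e-12)
  expect_lt(sum(csm$y_axis * (c(-80, 120, 0) - csm$origin)), 0)
})

test_that("cylinder fitting recovers exact and noisy cylinders", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- do.call(rbind, lapply(seq(0, 50, 10), function(z) {
    cbind(12 * cos(th), 12 * sin(th), z)
  }))
  fit <- fit_cylinder(pts)
  expect_equal(fit$radius, 12, tolerance = 1e-6)
  expect_lt(acos(min(abs(sum(fit$axis_direction * c(0, 0, 1))), 1)), 1e-6)
  expect_lt(fit$rms_residual, 1e-8)

  # Monte-Carlo recovery under noise: median over seeded replicates
  set.seed(1234)
  errs <- t(replicate(50, {
    noisy <- pts + matrix(rnorm(length(pts), sd = 0.2), ncol = 3)
    f <- fit_cylinder(noisy)
    c(abs(f$radius - 12),
      acos(min(abs(sum(f$axis_direction * c(0, 0, 1))), 1)) * 180 / pi)
  }))
  expect_lt(median(errs[, 1]), 0.1)   # radius within 0.1 mm
  expect_lt(median(errs[, 2]), 0.5)   # axis within 0.5 degrees

  expect_error(fit_cylinder(cbind(runif(20), runif(20), 0)), "coplanar")
  expect_error(fit_cylinder(cbind(1:20, 0, 0)), "collinear|coplanar")
  expect_error(fit_cylinder(pts[1:5, ]), "at least 8")
})

test_that("the humeral frame orients superiorly and clocks anterior to the tuberosity", {
  shaft <- list(axis_point = c(0, -50, 0), axis_direction = c(0, -1, 0))
  cs <- build_humeral_cs(c(0, 0, 0), shaft, c(10, 0, 0))
  expect_equal(cs$y_axis, c(0, 1, 0))   # flipped toward the head
  expect_equal(cs$x_axis, c(1, 0, 0))
  expect_equal(cs$z_axis, c(0, 0, 1))

  set.seed(11)
  T <- rigid_transform_random()
  tp <- function(p) drop(musclewrap:::apply_transform(T, p))
  R <- T[1:3, 1:3]
  cs2 <- build_humeral_cs(
    tp(c(0, 0, 0)),
    list(axis_point = tp(c(0, -50, 0)), axis_direction = drop(R %*% c(0, -1, 0))),
    tp(c(10, 0, 0))
  )
  expect_equal(cs2$y_axis, drop(R %*% cs$y_axis), tolerance = 1e-9)
  expect_equal(cs2$x_axis, drop(R %*% cs$x_axis), tolerance = 1e-9)

  expect_error(build_humeral_cs(c(0, 0, 0), shaft, c(0, -20, 0)), "collinear")
})
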