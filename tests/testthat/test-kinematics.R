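test_that("rodrigues matches the matrix exponential and its algebra", {
  # trivial anchors
  expect_equal(rodrigues(c(0, 0, 1), 0), diag(4), tolerance = 1e-15)
  expect_equal(drop(musclewrap:::apply_transform(
    rodrigues(c(0, 0, 1), pi / 2), c(1, 0, 0)
  )), c(0, 1, 0), tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:25) {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -2 * pi, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- rodrigues(ax, th)[1:3, 1:3]
    expect_lt(max(abs(R - as.matrix(Matrix::expm(th * K)))), 1e-10)
    # group properties
    ph <- runif(1, -pi, pi)
    expect_lt(max(abs(
      rodrigues(ax, th) %*% rodrigues(ax, ph) - rodrigues(ax, th + ph)
    )), 1e-9)
    expect_equal(drop(R %*% ax), ax, tolerance = 1e-10)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  # pivot preservation
  piv <- c(3, -4, 5)
  T <- rodrigues(c(1, 0, 0), 1.1, piv)
  expect_equal(drop(musclewrap:::apply_transform(T, piv)), piv, tolerance = 1e-12)
  expect_error(rodrigues(c(0, 0, 0), 1), "zero")
})

test_that("pose_body is rigid and track_probe follows its body", {
  sph <- mesh_icosphere(10, c(2, 0, 0), 2, "ball")
  frames <- list(diag(4), rodrigues(c(0, 0, 1), pi, c(2, 0, 0)),
                 rodrigues(c(1, 1, 0) / sqrt(2), 0.8, c(-1, 5, 2)))
  mo <- rigid_motion("ball", frames)

  expect_equal(pose_body(sph, mo, 1)$vertices, sph$vertices)
  expect_error(pose_body(sph, mo, 4), "out of range")

  # a symmetry rotation about the sphere centre permutes the vertex set
  # (180 degrees about z is a 2-fold axis of the subdivided icosahedron)
  p2 <- pose_body(sph, mo, 2)
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = ","))
  expect_identical(key(p2$vertices), key(sph$vertices))

  # pairwise distances preserved for an arbitrary frame
  p3 <- pose_body(sph, mo, 3)
  idx <- cbind(1:40, 41:80)
  d0 <- sqrt(rowSums((sph$vertices[idx[, 1], ] - sph$vertices[idx[, 2], ])^2))
  d3 <- sqrt(rowSums((p3$vertices[idx[, 1], ] - p3$vertices[idx[, 2], ])^2))
  expect_equal(d3, d0, tolerance = 1e-9)

  pr <- probe("center", "ball", c(2, 0, 0))
  expect_equal(track_probe(pr, mo, 1), c(2, 0, 0))
  expect_equal(track_probe(pr, mo, 2), c(2, 0, 0), tolerance = 1e-9) # on the pivot
  tr <- rigid_motion("ball", list(diag(4), {
    T <- diag(4); T[1:3, 4] <- c(1, 2, 3); T
  }))
  expect_equal(track_probe(pr, tr, 2), c(3, 2, 3))
  expect_error(track_probe(probe("p", "other", c(0, 0, 0)), mo, 1), "belongs to")
})
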