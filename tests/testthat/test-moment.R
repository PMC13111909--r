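test_that("muscle length sums segments and matches the arc oracle", {
  expect_equal(muscle_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  straight <- cbind(seq(0, 10, length.out = 101), 2, -1)
  expect_equal(muscle_length(straight), 10, tolerance = 1e-12)
  th <- seq(0, pi, length.out = 101)
  semi <- cbind(30 * cos(th), 30 * sin(th), 0)
  expect_lt(abs(muscle_length(semi) - pi * 30) / (pi * 30), 5e-4)
})

test_that("departure refinement finds the foot of the perpendicular", {
  expect_equal(refine_departure(c(5, 3, 0), c(1, 0, 0), c(0, 0, 0)), c(0, 3, 0))
  expect_equal(refine_departure(c(0, 3, 0), c(1, 0, 0), c(0, 0, 0)), c(0, 3, 0))
  set.seed(21)
  for (rep in 1:10) {
    p <- rnorm(3, sd = 10)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    cor <- rnorm(3, sd = 10)
    ref <- refine_departure(p, u, cor)
    expect_lt(abs(sum((ref - cor) * u)), 1e-10)
    # brute-force 1-D sweep over the line of action
    tt <- seq(-100, 100, length.out = 400001)
    d2 <- colSums((outer(p, rep(1, length(tt))) + outer(u, tt) - cor)^2)
    tstar <- tt[which.min(d2)]
    expect_equal(sum((ref - p) * u), tstar, tolerance = 1e-3)
    expect_equal(resultant_moment_arm(ref, u, cor), sqrt(min(d2)), tolerance = 1e-6)
  }
})

test_that("resultant moment arms: zero through the centre, radius when tangent", {
  expect_equal(resultant_moment_arm(c(0, 5, 0), c(0, 1, 0), c(0, 0, 0)), 0)
  expect_equal(resultant_moment_arm(c(30, 0, 0), c(0, 0, 1), c(0, 0, 0)), 30)
})

test_that("decomposition closes under Pythagoras and respects parallel axes", {
  # component about an axis parallel to the line of action is zero
  d <- decompose_moment_arm(c(30, 0, 0), c(0, 1, 0), c(0, 0, 0),
                            list(elevation = c(0, 1, 0), plane = c(0, 0, 1),
                                 axial = c(0, 0, 1)))
  expect_equal(unname(d[["ma_elevation"]]), 0)
  set.seed(33)
  for (rep in 1:10) {
    p <- rnorm(3, sd = 20)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    cor <- rnorm(3, sd = 5)
    ref <- refine_departure(p, u, cor)
    # random orthonormal right-handed triad
    R <- rodrigues(rnorm(3), runif(1, 0, 2 * pi))[1:3, 1:3]
    axes <- list(elevation = R[, 1], plane = R[, 2], axial = R[, 3])
    d <- decompose_moment_arm(ref, u, cor, axes)
    ma <- resultant_moment_arm(ref, u, cor)
    expect_equal(sum(d^2), ma^2, tolerance = 1e-9)
    expect_true(all(abs(d) <= ma + 1e-12))
    # resultant invariant under a rigid transform of the whole configuration
    T <- rigid_transform_random()
    tp <- function(x) drop(musclewrap:::apply_transform(T, x))
    expect_equal(
      resultant_moment_arm(tp(ref), drop(T[1:3, 1:3] %*% u), tp(cor)),
      ma, tolerance = 1e-9
    )
  }
})

test_that("departure jumps are flagged exactly where injected", {
  recs <- do.call(rbind, lapply(0:19, function(k) {
    moment_arm_record(k, k * 0.1, "m", 100, 30, 1, 2, 3,
                      c(10 + 0.3 * k, 0, 5), c(0, 0, 1))
  }))
  expect_true(all(flag_discontinuities(recs, 5)$flags == ""))
  recs2 <- recs
  recs2[recs2$frame >= 12, c("departure_x")] <- recs2[recs2$frame >= 12, "departure_x"] + 15
  out <- flag_discontinuities(recs2, 5)
  expect_identical(which(out$flags == "departure_jump"), 13L) # frame 12 only
})

test_that("axial moment arms equal tendon excursion on the fine-sheet run", {
  res <- fine_sheet_constrained_run()
  r <- res$records
  step_rad <- res$scene$meta$spec$step_deg * pi / 180
  for (m in unique(r$muscle)) {
    s <- r[r$muscle == m, ]
    s <- s[order(s$frame), ]
    L <- s$length_mm
    n <- length(L)
    dL <- (L[-(1:2)] - L[1:(n - 2)]) / (2 * step_rad)
    ax <- s$ma_axial_mm[2:(n - 1)]
    expect_lt(max(abs(-dL - ax) / abs(ax)), 0.02)
  }
})
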