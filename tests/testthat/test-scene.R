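test_that("scene validation fails iff a referenced body or probe is missing", {
  ball <- mesh_icosphere(5, c(0, 0, 0), 1, "ball")
  blade <- mesh_box(c(-20, 0, 0), c(5, 10, 10), "blade")
  probes <- list(probe("o", "blade", c(-17, 0, 0)), probe("i", "ball", c(0, 0, 6)))
  mus <- list(muscle_spec("m", "o", "i", "ball"))
  motion <- list(rigid_motion("ball", list(diag(4))))

  expect_s3_class(scene(list(ball = ball, blade = blade), motion, probes, mus), "scene")
  # every deletion of a referenced body must fail
  expect_error(scene(list(blade = blade), motion, probes, mus), "missing body")
  expect_error(scene(list(ball = ball), motion, probes[1], mus), "missing body")
  # unknown probe in a muscle spec
  expect_error(
    scene(list(ball = ball, blade = blade), motion, probes[1], mus),
    "missing probe"
  )
  # unequal frame counts across motions
  expect_error(
    scene(list(ball = ball, blade = blade),
          c(motion, list(rigid_motion("blade", list(diag(4), diag(4))))),
          probes, mus),
    "unequal frame counts"
  )
})

test_that("a YAML scene configuration round-trips through read_scene_config", {
  dir <- tempfile("scene")
  cfg <- write_synthetic_scene_config(dir)
  sc <- read_scene_config(cfg)
  expect_setequal(names(sc$bodies), c("ball", "blade"))
  expect_equal(scene_n_frames(sc), 11L)
  expect_equal(sc$muscles$wrapper$obstacles, "ball")
  expect_equal(scene_probe_position(sc, "cor", 5), c(0, 0, 0))
  expect_equal(sc$meta$landmarks$center_of_rotation, "cor")
})
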