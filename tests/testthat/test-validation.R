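test_that("the verification scene is built to specification", {
  sc <- build_validation_scene()
  expect_equal(scene_n_frames(sc), 91L)             # 0..90 degrees at 1 degree
  expect_setequal(names(sc$bodies), c("humerus", "scapula"))
  expect_length(sc$muscles, 3L)
  expect_s3_class(validate_scene(sc), "scene")

  # sphere surface fidelity at subdivision 5: max radial deviation of the
  # mesh (face centroids included) below 0.05 mm
  sph <- mesh_icosphere(30, c(0, 0, 0), 5, "s")
  v <- sph$vertices
  f <- sph$faces
  centroids <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  dev <- abs(sqrt(rowSums(rbind(v, centroids)^2)) - 30)
  expect_lt(max(dev), 0.05)

  # insertions placed so chords never penetrate -> refused
  expect_error(build_validation_scene(validation_spec(insertion_azimuth_deg = 150)),
               "lines never wrap")
  expect_error(validation_spec(step_deg = 7), "divide")
})

test_that("summary deltas are stable under step halving", {
  s10 <- run_validation(validation_spec(step_deg = 10))$summary
  s5 <- run_validation(validation_spec(step_deg = 5))$summary
  for (f in c("max_ma_deviation", "max_constrained_component_error",
              "max_length_difference")) {
    expect_lt(abs(s5[[f]] - s10[[f]]), 0.05)
  }
})

test_that("cmd_validate honours spec overrides and flags broken configs", {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(step_deg = 5), tmp)
  out <- tempfile("vout")
  expect_equal(suppressMessages(cmd_validate(tmp, out_dir = out)), 0L)
  expect_true(file.exists(file.path(out, "validation_results.csv")))
  summ <- jsonlite::read_json(file.path(out, "validation_summary.json"))
  expect_true(summ$pass)
  expect_lt(summ$max_ma_deviation, 0.3)

  bad <- tempfile(fileext = ".yaml")
  writeLines("step_deg: [unclosed", bad)
  expect_equal(suppressMessages(cmd_validate(bad)), 2L)
})

test_that("externally supplied meshes and kinematics run end to end", {
  dir <- tempfile("ingest")
  cfg <- write_synthetic_scene_config(dir)
  out <- file.path(dir, "out")
  expect_equal(suppressMessages(cmd_run(cfg, out_dir = out)), 0L)
  res <- read_results(file.path(out, "results.csv"))
  expect_identical(names(res), musclewrap:::RESULT_COLUMNS)
  expect_equal(nrow(res), 11L)
  expect_true(all(is.finite(res$moment_arm_mm)))
  expect_true(all(is.finite(res$ma_axial_mm)))
  expect_true(file.exists(file.path(out, "summary.json")))

  # frame selection: 0-based inclusive range
  out2 <- file.path(dir, "out2")
  expect_equal(suppressMessages(cmd_run(cfg, out_dir = out2, frames = "0:4")), 0L)
  expect_equal(nrow(read_results(file.path(out2, "results.csv"))), 5L)

  # missing mesh file -> configuration error
  cfg2 <- file.path(dir, "broken.yaml")
  y <- yaml::read_yaml(cfg)
  y$bodies$ball$stl <- "missing.stl"
  yaml::write_yaml(y, cfg2)
  expect_equal(suppressMessages(cmd_run(cfg2, out_dir = out)), 2L)
})
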