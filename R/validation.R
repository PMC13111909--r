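#' Verification-model specification
#'
#' Parameters of the programmatic verification scene: a rectangular prism
#' standing in for the scapula and a 30 mm sphere on a stick standing in for
#' the humerus, with three subscapularis-like muscle lines (superior,
#' bisector, inferior) wrapping the sphere while the sphere/stick externally
#' rotates about the stick axis.
#'
#' The default geometry is chosen from tangent geometry so that every line's
#' straight chord penetrates the sphere at every frame, wrapped contact arcs
#' stay below 180 degrees (locally stable wrap), and the free wrap visibly
#' splays away from its lane plane at end range while the sheet-guided wrap
#' does not.
#'
#' @param sphere_radius humeral sphere radius (mm).
#' @param stick_radius,stick_y stick (shaft) radius and axial extent (mm,
#'   along -y from the sphere).
#' @param prism_center,prism_dims scapula prism centre and extents (mm).
#' @param origin_x x-coordinate of the muscle origins, just lateral of the
#'   prism face.
#' @param lateral_offset superior/inferior line offset from the bisector
#'   plane (mm).
#' @param insertion_radius distance of the insertions from the stick axis (mm).
#' @param insertion_azimuth_deg initial insertion azimuth in the x-z plane,
#'   degrees from +x toward +z (the origins sit at azimuth 180).
#' @param rotation_deg total external rotation (degrees).
#' @param step_deg rotation increment (degrees); must divide `rotation_deg`.
#' @param mesh_subdivisions icosphere subdivision level of the sphere mesh.
#' @param n_segments muscle-line segments.
#' @param sheet_lanes,sheet_subdivisions sheet grid resolution.
#' @param pretension_scale sheet rest-length scale; 1 (no pre-tension) here,
#'   since the convex sphere cannot buckle the sheet.
#' @return A list of class `validation_spec`.
#' @export
validation_spec <- function(sphere_radius = 30, stick_radius = 6,
                            stick_y = c(-80, -29.5),
                            prism_center = c(-40.4, 0, 0),
                            prism_dims = c(9.2, 50, 40),
                            origin_x = -35, lateral_offset = 7.5,
                            insertion_radius = 34, insertion_azimuth_deg = 110,
                            rotation_deg = 90, step_deg = 1,
                            mesh_subdivisions = 5, n_segments = 100,
                            sheet_lanes = 5, sheet_subdivisions = 50,
                            pretension_scale = 1) {
  stopifnot(sphere_radius > 0, insertion_radius > sphere_radius,
            rotation_deg > 0, step_deg > 0)
  if (rotation_deg %% step_deg != 0) stop("step_deg must divide rotation_deg")
  structure(as.list(environment()), class = "validation_spec")
}

#' Build the verification scene
#'
#' Two bodies (sphere-on-stick "humerus", prism "scapula"), three muscle
#' lines, landmark probes for the anatomic frames, and incremental Rodrigues
#' external rotation of the humerus about the stick axis. Errors if any
#' line's straight chord fails to penetrate the sphere at some frame
#' ("lines never wrap").
#'
#' @param spec a [validation_spec].
#' @return A [scene]; `meta` carries the spec, landmark roles and sheet lanes.
#' @export
build_validation_scene <- function(spec = validation_spec()) {
  R <- spec$sphere_radius
  sphere <- mesh_icosphere(R, c(0, 0, 0), spec$mesh_subdivisions, "humerus")
  stick <- mesh_cylinder(spec$stick_radius, c(0, spec$stick_y[1], 0),
                         c(0, spec$stick_y[2], 0))
  humerus <- mesh_merge(sphere, stick, body_name = "humerus")
  scapula <- mesh_box(spec$prism_center, spec$prism_dims, "scapula")

  angles <- seq(0, spec$rotation_deg, by = spec$step_deg)
  frames <- lapply(angles * pi / 180, function(a) rodrigues(c(0, 1, 0), a))
  motions <- list(
    rigid_motion("humerus", frames, timestamps = angles),
    static_motion("scapula", length(frames), timestamps = angles)
  )

  az <- spec$insertion_azimuth_deg * pi / 180
  offs <- c(superior = spec$lateral_offset, bisector = 0,
            inferior = -spec$lateral_offset)
  probes <- list(
    probe("trigonum", "scapula", c(spec$prism_center[1] - spec$prism_dims[1] / 2, 0, 0)),
    probe("inferior_angle", "scapula",
          c(spec$prism_center[1] - spec$prism_dims[1] / 2, -20, 0)),
    probe("glenoid_center", "scapula", c(spec$origin_x, 0, 0)),
    probe("head_center", "humerus", c(0, 0, 0)),
    probe("lesser_tuberosity", "humerus",
          c(R * cos(100 * pi / 180), 5, R * sin(100 * pi / 180)))
  )
  muscles <- list()
  for (nm in names(offs)) {
    y0 <- offs[[nm]]
    probes <- c(probes, list(
      probe(paste0(nm, "_origin"), "scapula", c(spec$origin_x, y0, 0)),
      probe(paste0(nm, "_insertion"), "humerus",
            c(spec$insertion_radius * cos(az), y0, spec$insertion_radius * sin(az)))
    ))
    muscles <- c(muscles, list(
      muscle_spec(nm, paste0(nm, "_origin"), paste0(nm, "_insertion"),
                  c("humerus", "scapula"))
    ))
  }
  sc <- scene(
    bodies = list(humerus = humerus, scapula = scapula),
    motions = motions, probes = probes, muscles = muscles,
    meta = list(
      spec = spec,
      landmarks = list(
        trigonum = "trigonum", inferior_angle = "inferior_angle",
        glenoid_center = "glenoid_center", center_of_rotation = "head_center",
        lesser_tuberosity = "lesser_tuberosity",
        shaft_body = "humerus", shaft_y_range = c(-75, -35)
      ),
      sheet = list(
        lane_offsets = seq(-spec$lateral_offset, spec$lateral_offset,
                           length.out = spec$sheet_lanes),
        attach = list(start = "scapula", end = "humerus")
      )
    )
  )
  # every line's straight chord must penetrate the sphere at every frame
  for (mu in sc$muscles) {
    O <- scene_probe_position(sc, mu$origin, 1L)
    for (k in seq_along(frames)) {
      I <- scene_probe_position(sc, mu$insertion, k)
      if (segment_point_distance(O, I, c(0, 0, 0)) >= R) {
        stop("lines never wrap: '", mu$name, "' chord misses the sphere at frame ", k)
      }
    }
  }
  sc
}

segment_point_distance <- function(a, b, p) {
  d <- b - a
  t <- sum((p - a) * d) / sum(d * d)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * d - p)^2))
}

#' Run the verification experiment
#'
#' Wraps the three muscle lines at every frame of the external rotation, in
#' unconstrained and/or sheet-constrained mode, assembles per-frame
#' moment-arm records (resultant and decomposed about the scapular axes and
#' the rotating humeral shaft axis), and compares against the closed-form
#' lane-plane tangent-geometry expectation.
#'
#' @param spec a [validation_spec].
#' @param modes subset of `c("unconstrained", "constrained")`.
#' @param wrap a [wrap_params]; defaults derive from the spec.
#' @param sheet_params a [sheet_solver_params].
#' @param progress print a line every 10 frames.
#' @return A list with `records` (data frame; one row per frame, line and
#'   mode, including `exp_*` analytic-expectation columns), `summary` (the
#'   verification deltas), `scene` and `sheet`.
#' @export
run_validation <- function(spec = validation_spec(),
                           modes = c("unconstrained", "constrained"),
                           wrap = NULL, sheet_params = sheet_solver_params(),
                           progress = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  sc <- build_validation_scene(spec)
  if (is.null(wrap)) wrap <- wrap_params(n_segments = spec$n_segments)
  n_frames <- scene_n_frames(sc)
  R <- spec$sphere_radius
  lm <- sc$meta$landmarks
  axis_y <- c(0, 1, 0)

  # anatomic frames: static scapular CS; humeral shaft cylinder fit in the
  # reference pose, re-posed per frame
  scap_cs <- build_scapular_cs(
    scene_probe_position(sc, lm$trigonum, 1L),
    scene_probe_position(sc, lm$inferior_angle, 1L),
    scene_probe_position(sc, lm$glenoid_center, 1L)
  )
  hv <- sc$bodies[[lm$shaft_body]]$vertices
  shaft_pts <- hv[hv[, 2] >= lm$shaft_y_range[1] & hv[, 2] <= lm$shaft_y_range[2], ]
  shaft_fit <- fit_cylinder(shaft_pts)
  hum_motion <- scene_motion(sc, lm$shaft_body)

  mus <- sc$muscles
  bindings <- vector("list", length(mus))
  names(bindings) <- names(mus)
  warm <- list()
  sheet <- NULL
  lane_curves <- NULL
  rows <- list()

  for (k in seq_len(n_frames)) {
    Tk <- motion_transform(hum_motion, k)
    obstacles <- list(pose_body(sc$bodies$humerus, hum_motion, k), sc$bodies$scapula)
    cor <- scene_probe_position(sc, lm$center_of_rotation, k)
    lt <- scene_probe_position(sc, lm$lesser_tuberosity, k)
    shaft_k <- shaft_fit
    shaft_k$axis_direction <- drop(Tk[1:3, 1:3] %*% shaft_fit$axis_direction)
    shaft_k$axis_point <- drop(apply_transform(Tk, shaft_fit$axis_point))
    hum_cs <- build_humeral_cs(cor, shaft_k, lt)
    axes <- list(elevation = scap_cs$x_axis, plane = scap_cs$y_axis,
                 axial = hum_cs$y_axis)
    time_s <- if (!is.null(hum_motion$timestamps)) hum_motion$timestamps[k] else NA_real_

    # wrap the free lines (the frame-0 wrap also seeds the sheet binding,
    # so it is computed even in constrained-only runs)
    lines_u <- list()
    if ("unconstrained" %in% modes || k == 1L) {
      for (mu in mus) {
        O <- scene_probe_position(sc, mu$origin, k)
        I <- scene_probe_position(sc, mu$insertion, k)
        ln <- wrap_line(O, I, obstacles, wrap, name = mu$name, init = warm[[mu$name]])
        warm[[mu$name]] <- ln$nodes
        lines_u[[mu$name]] <- find_departure(ln, "humerus")
      }
    }

    if ("constrained" %in% modes && is.null(sheet)) {
      # build the rest sheet at the reference frame from lane wrap curves
      stopifnot(k == 1L)
      laneO <- sc$meta$sheet$lane_offsets
      lane_curves <- lapply(laneO, function(y0) {
        o <- c(spec$origin_x, y0, 0)
        az <- spec$insertion_azimuth_deg * pi / 180
        i <- c(spec$insertion_radius * cos(az), y0, spec$insertion_radius * sin(az))
        wrap_line(o, i, obstacles,
                  wrap_params(n_segments = spec$sheet_subdivisions,
                              convergence_tol_mm = wrap$convergence_tol_mm,
                              contact_tol_mm = wrap$contact_tol_mm),
                  name = sprintf("lane_%g", y0))$nodes
      })
      sheet <- loft_sheet(lane_curves, attach = sc$meta$sheet$attach,
                          material = sheet_material(),
                          pretension_scale = spec$pretension_scale)
      for (mu in mus) bindings[[mu$name]] <- bind_line_to_sheet(lines_u[[mu$name]], sheet)
    }

    buck <- integer(0)
    if ("constrained" %in% modes) {
      sheet <- relax_sheet(sheet, obstacles,
                           poses = list(humerus = Tk), params = sheet_params)
      buck <- detect_buckling(sheet)
    }

    for (mu in mus) {
      y0 <- sc$probes[[mu$origin]]$local_position[2]
      O <- scene_probe_position(sc, mu$origin, k)
      I <- scene_probe_position(sc, mu$insertion, k)
      exp_cw <- circle_wrap(O, I, cor + y0 * axis_y, sqrt(R^2 - y0^2), axis_y)
      expd <- decompose_moment_arm(refine_departure(exp_cw$departure, exp_cw$uvec, cor),
                                   exp_cw$uvec, cor, axes)
      for (mode in modes) {
        ln <- if (mode == "unconstrained") lines_u[[mu$name]] else {
          cl <- constrain_line_to_sheet(lines_u[[mu$name]], sheet,
                                        binding = bindings[[mu$name]],
                                        obstacles = obstacles,
                                        target_body = "humerus")
          if (length(buck)) cl$flags <- union(cl$flags, "buckling")
          cl
        }
        p <- refine_departure(ln$departure_point, ln$departure_uvec, cor)
        ma <- resultant_moment_arm(p, ln$departure_uvec, cor)
        dec <- decompose_moment_arm(p, ln$departure_uvec, cor, axes)
        rec <- moment_arm_record(
          frame = k - 1L, time_s = time_s, muscle = mu$name,
          length_mm = ln$length_mm, moment_arm_mm = ma,
          ma_elevation_mm = dec[["ma_elevation"]],
          ma_plane_mm = dec[["ma_plane"]], ma_axial_mm = dec[["ma_axial"]],
          departure_point = p, departure_uvec = ln$departure_uvec,
          flags = ln$flags
        )
        rec$mode <- mode
        rec$exp_elevation <- expd[["ma_elevation"]]
        rec$exp_plane <- expd[["ma_plane"]]
        rec$exp_axial <- expd[["ma_axial"]]
        rec$exp_length <- exp_cw$length
        rows[[length(rows) + 1L]] <- rec
      }
    }
    if (progress && (k %% 10L == 1L)) {
      cat(sprintf("frame %d/%d\n", k, n_frames))
    }
  }
  records <- do.call(rbind, rows)
  # discontinuity flags per muscle and mode
  out <- NULL
  for (mode in unique(records$mode)) {
    for (nm in names(mus)) {
      sub <- records[records$mode == mode & records$muscle == nm, ]
      sub <- flag_discontinuities(sub[order(sub$frame), ])
      out <- rbind(out, sub)
    }
  }
  records <- out[order(out$mode, out$muscle, out$frame), ]
  rownames(records) <- NULL
  list(records = records, summary = summarize_validation(records, R, modes),
       scene = sc, sheet = sheet)
}

comp_errors <- function(records) {
  cbind(abs(records$ma_elevation_mm - records$exp_elevation),
        abs(records$ma_plane_mm - records$exp_plane),
        abs(records$ma_axial_mm - records$exp_axial))
}

summarize_validation <- function(records, sphere_radius, modes) {
  s <- list(sphere_radius = sphere_radius)
  s$max_ma_deviation <- max(abs(records$moment_arm_mm - sphere_radius))
  con <- records[records$mode == "constrained" |
                   (records$mode == "unconstrained" & records$muscle == "bisector"), ]
  s$max_constrained_component_error <- if (nrow(con)) max(comp_errors(con)) else NA_real_
  lat <- records[records$mode == "unconstrained" & records$muscle != "bisector", ]
  s$max_unconstrained_component_error <- if (nrow(lat)) max(comp_errors(lat)) else NA_real_
  if (all(c("unconstrained", "constrained") %in% modes)) {
    key <- interaction(records$muscle, records$frame)
    lu <- records$length_mm[records$mode == "unconstrained"][order(key[records$mode == "unconstrained"])]
    lc <- records$length_mm[records$mode == "constrained"][order(key[records$mode == "constrained"])]
    s$max_length_difference <- max(abs(lu - lc))
  } else {
    s$max_length_difference <- NA_real_
  }
  s$flag_tokens <- sort(unique(unlist(strsplit(records$flags[nzchar(records$flags)], ";"))))
  s
}
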