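#' Point probe attached to a body
#'
#' @param name probe identifier.
#' @param body_name body the probe is rigidly attached to.
#' @param local_position position in the body's frame-0 coordinates (mm).
#' @return An object of class `probe`.
#' @export
probe <- function(name, body_name, local_position) {
  stopifnot(length(local_position) == 3L)
  structure(
    list(name = as.character(name), body_name = as.character(body_name),
         local_position = as.numeric(local_position)),
    class = "probe"
  )
}

#' Muscle line specification
#'
#' @param name muscle line identifier.
#' @param origin,insertion probe names for the fixed end points.
#' @param obstacles character vector of body names the line must wrap around.
#' @param constraint `"unconstrained"` or `"constrained"` (sheet-guided).
#' @return An object of class `muscle_spec`.
#' @export
muscle_spec <- function(name, origin, insertion, obstacles,
                        constraint = c("unconstrained", "constrained")) {
  constraint <- match.arg(constraint)
  structure(
    list(name = as.character(name), origin = origin, insertion = insertion,
         obstacles = as.character(obstacles), constraint = constraint),
    class = "muscle_spec"
  )
}

#' Scene: bodies, motions, probes and muscle specifications
#'
#' The container every other module consumes. Bodies without a motion are
#' static (identity transforms at every frame).
#'
#' @param bodies named list of [trimesh] objects (names are body names).
#' @param motions list of [rigid_motion] objects.
#' @param probes list of [probe] objects.
#' @param muscles list of [muscle_spec] objects.
#' @param meta free-form list of scene metadata (e.g. landmark roles).
#' @return An object of class `scene`.
#' @export
scene <- function(bodies, motions = list(), probes = list(), muscles = list(),
                  meta = list()) {
  names(bodies) <- vapply(bodies, `[[`, "", "body_name")
  names(motions) <- vapply(motions, `[[`, "", "body_name")
  names(probes) <- vapply(probes, `[[`, "", "name")
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  sc <- structure(
    list(bodies = bodies, motions = motions, probes = probes, muscles = muscles,
         meta = meta),
    class = "scene"
  )
  validate_scene(sc)
  sc
}

#' Validate a scene
#'
#' Fails if and only if a referenced body is missing, motions have unequal
#' frame counts, or a muscle spec references an unknown probe.
#'
#' @param sc a [scene].
#' @return `sc`, invisibly, or an error.
#' @export
validate_scene <- function(sc) {
  body_names <- names(sc$bodies)
  for (m in sc$motions) {
    if (!m$body_name %in% body_names) stop("motion references missing body '", m$body_name, "'")
  }
  nf <- vapply(sc$motions, function(m) length(m$frames), 1L)
  if (length(nf) > 1L && length(unique(nf)) != 1L) {
    stop("motions have unequal frame counts: ", paste(nf, collapse = ", "))
  }
  for (p in sc$probes) {
    if (!p$body_name %in% body_names) {
      stop("probe '", p$name, "' references missing body '", p$body_name, "'")
    }
  }
  for (mu in sc$muscles) {
    for (pn in c(mu$origin, mu$insertion)) {
      if (!pn %in% names(sc$probes)) {
        stop("muscle '", mu$name, "' references missing probe '", pn, "'")
      }
    }
    for (b in mu$obstacles) {
      if (!b %in% body_names) {
        stop("muscle '", mu$name, "' references missing body '", b, "'")
      }
    }
  }
  invisible(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "scene: %d bodies, %d motions (%d frames), %d probes, %d muscle lines\n",
    length(x$bodies), length(x$motions), scene_n_frames(x), length(x$probes),
    length(x$muscles)
  ))
  invisible(x)
}

#' Number of frames in a scene
#'
#' @param sc a [scene].
#' @return Integer frame count (1 when no motions are present).
#' @export
scene_n_frames <- function(sc) {
  if (length(sc$motions) == 0L) return(1L)
  length(sc$motions[[1]]$frames)
}

# motion of a body; static bodies get identity frames
scene_motion <- function(sc, body_name, n_frames = scene_n_frames(sc)) {
  if (body_name %in% names(sc$motions)) sc$motions[[body_name]]
  else static_motion(body_name, n_frames)
}

#' World position of a named probe at a frame
#'
#' @param sc a [scene].
#' @param probe_name probe identifier.
#' @param frame 1-based frame index.
#' @return Length-3 world position.
#' @export
scene_probe_position <- function(sc, probe_name, frame) {
  p <- sc$probes[[probe_name]]
  if (is.null(p)) stop("unknown probe '", probe_name, "'")
  track_probe(p, scene_motion(sc, p$body_name), frame)
}

#' Read a scene from a YAML configuration
#'
#' The configuration names STL meshes and kinematics text files per body,
#' probes with local positions, and muscle specifications:
#' \preformatted{
#' bodies:
#'   humerus: {stl: humerus.stl, kinematics: humerus.txt}
#'   scapula: {stl: scapula.stl}
#' probes:
#'   origin_1: {body: scapula, position: [-35, 0, 0]}
#' muscles:
#'   subscap_mid: {origin: origin_1, insertion: ins_1,
#'                 obstacles: [humerus], constraint: unconstrained}
#' landmarks:   # optional; enables decomposed moment arms
#'   trigonum: ts_probe
#'   inferior_angle: ia_probe
#'   glenoid_center: gc_probe
#'   center_of_rotation: cor_probe
#'   lesser_tuberosity: lt_probe
#'   shaft_points: [shaft_top, shaft_bottom]  # or shaft_body + shaft_range
#' }
#'
#' @param path YAML file path; relative file references are resolved against
#'   its directory.
#' @return A [scene].
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (file.exists(f)) f else file.path(base, f)
  if (is.null(cfg$bodies) || length(cfg$bodies) == 0) stop("config has no bodies")
  bodies <- list()
  motions <- list()
  for (bn in names(cfg$bodies)) {
    b <- cfg$bodies[[bn]]
    if (is.null(b$stl)) stop("body '", bn, "' has no stl entry")
    bodies[[bn]] <- read_stl(rel(b$stl), body_name = bn)
    if (!is.null(b$kinematics)) {
      motions[[bn]] <- read_kinematics(rel(b$kinematics), bn)
    }
  }
  probes <- lapply(names(cfg$probes %||% list()), function(pn) {
    p <- cfg$probes[[pn]]
    probe(pn, p$body, as.numeric(p$position))
  })
  muscles <- lapply(names(cfg$muscles %||% list()), function(mn) {
    m <- cfg$muscles[[mn]]
    muscle_spec(mn, m$origin, m$insertion, unlist(m$obstacles),
                m$constraint %||% "unconstrained")
  })
  meta <- cfg[setdiff(names(cfg), c("bodies", "probes", "muscles"))]
  scene(bodies, motions, probes, muscles, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
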