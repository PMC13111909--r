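#' Wrapping algorithm parameters
#'
#' @param n_segments number of line segments the path is discretized into
#'   (101 nodes at the default 100).
#' @param max_iterations iteration cap for the relaxation.
#' @param convergence_tol_mm stop when the largest node displacement in one
#'   sweep falls below this (mm).
#' @param contact_tol_mm nodes within this signed distance of a body's offset
#'   surface are classified as contacting it (mm).
#' @param line_radius_mm offset of the wrapping surface outward from the bone
#'   along the local normal, modelling a finite muscle-line radius.
#' @param relaxation over-relaxation factor in `[1, 2)` applied to the
#'   neighbour-averaging step (a solver acceleration; the converged path is
#'   the same fixed point as plain averaging).
#' @return An object of class `wrap_params`.
#' @export
wrap_params <- function(n_segments = 100, max_iterations = 10000,
                        convergence_tol_mm = 1e-4, contact_tol_mm = 0.1,
                        line_radius_mm = 0, relaxation = 1.6) {
  stopifnot(n_segments >= 1, max_iterations >= 1, convergence_tol_mm > 0,
            contact_tol_mm > 0, line_radius_mm >= 0,
            relaxation >= 1, relaxation < 2)
  structure(
    list(n_segments = as.integer(n_segments),
         max_iterations = as.integer(max_iterations),
         convergence_tol_mm = convergence_tol_mm,
         contact_tol_mm = contact_tol_mm,
         line_radius_mm = line_radius_mm,
         relaxation = relaxation),
    class = "wrap_params"
  )
}

new_muscle_line <- function(name, nodes, params) {
  structure(
    list(name = name, nodes = nodes,
         n_segments = nrow(nodes) - 1L,
         contact_state = rep("free", nrow(nodes)),
         departure_index = NA_integer_,
         departure_point = c(NA_real_, NA_real_, NA_real_),
         departure_uvec = c(NA_real_, NA_real_, NA_real_),
         length_mm = polyline_length(nodes),
         flags = character(0),
         params = params),
    class = "muscle_line"
  )
}

#' @export
print.muscle_line <- function(x, ...) {
  cat(sprintf(
    "muscle_line '%s': %d segments, length %.3f mm, %d contact nodes%s\n",
    x$name, x$n_segments, x$length_mm, sum(x$contact_state != "free"),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]") else ""
  ))
  invisible(x)
}

polyline_length <- function(nodes) {
  if (nrow(nodes) < 2L) return(0)
  sum(sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-nrow(nodes), , drop = FALSE])^2)))
}

#' Wrap a muscle line around obstacle meshes
#'
#' Finds the locally shortest polyline between fixed end points that stays
#' outside the obstacle surfaces (offset outward by `line_radius_mm`). The
#' path is discretized into `n_segments` segments; each relaxation sweep moves
#' every interior node to the average of its two neighbours and projects it
#' back onto the nearest offset surface if it penetrates, until the largest
#' per-sweep displacement falls below the convergence tolerance. The solver
#' is deterministic: identical inputs give bitwise-identical node arrays.
#'
#' @param origin,insertion fixed end points in world coordinates (mm), which
#'   must lie strictly outside every obstacle.
#' @param obstacles list of [trimesh] obstacles (posed via [pose_body] as
#'   needed).
#' @param params a [wrap_params].
#' @param name muscle line identifier.
#' @param init optional node matrix from a previous solve (warm start); its
#'   interior nodes seed the relaxation.
#' @return A `muscle_line` with contact states, length, and (after
#'   [find_departure]) departure metadata. If the iteration cap is reached the
#'   line is returned with an `unconverged` flag and a warning.
#' @export
wrap_line <- function(origin, insertion, obstacles, params = wrap_params(),
                      name = "muscle", init = NULL) {
  origin <- as.numeric(origin)
  insertion <- as.numeric(insertion)
  for (ob in obstacles) {
    q <- mesh_query(ob, rbind(origin, insertion))
    if (any(q$sdist <= params$line_radius_mm)) {
      stop("endpoint inside obstacle '", ob$body_name, "'")
    }
  }
  n <- params$n_segments + 1L
  if (!is.null(init) && nrow(init) == n) {
    nodes <- init
    nodes[1, ] <- origin
    nodes[n, ] <- insertion
  } else {
    tt <- seq(0, 1, length.out = n)
    nodes <- cbind(
      origin[1] + tt * (insertion[1] - origin[1]),
      origin[2] + tt * (insertion[2] - origin[2]),
      origin[3] + tt * (insertion[3] - origin[3])
    )
  }
  sol <- .mw_wrap_solve(nodes, pack_obstacles(obstacles), params$line_radius_mm,
                        params$max_iterations, params$convergence_tol_mm,
                        params$relaxation %||% 1)
  line <- new_muscle_line(name, sol$nodes, params)
  if (!sol$converged) {
    line$flags <- c(line$flags, "unconverged")
    warning("wrap_line '", name, "' unconverged after ", sol$iterations,
            " iterations (max displacement ", signif(sol$max_disp, 3), " mm)")
  }
  classify_contacts(line, obstacles, params$contact_tol_mm)
}

#' Classify per-node contact state
#'
#' Labels each node with the nearest body whose offset signed distance is at
#' most `contact_tol_mm`, or `free`. Ties within 1e-12 mm go to the
#' lexicographically first body name (logged via `message`).
#'
#' @param line a `muscle_line`.
#' @param obstacles list of [trimesh] obstacles.
#' @param contact_tol_mm contact tolerance (mm).
#' @return The line with `contact_state` set.
#' @export
classify_contacts <- function(line, obstacles,
                              contact_tol_mm = line$params$contact_tol_mm) {
  n <- nrow(line$nodes)
  state <- rep("free", n)
  if (length(obstacles)) {
    lr <- line$params$line_radius_mm %||% 0
    nm <- vapply(obstacles, `[[`, "", "body_name")
    ord <- order(nm)
    sd <- vapply(obstacles[ord], function(ob) mesh_query(ob, line$nodes)$sdist - lr,
                 numeric(n))
    sd <- matrix(sd, nrow = n)
    best <- apply(sd, 1L, which.min)
    bestd <- sd[cbind(seq_len(n), best)]
    ties <- rowSums(abs(sd - bestd) < 1e-12) > 1L
    if (any(ties & bestd <= contact_tol_mm)) {
      message("contact tie at ", sum(ties & bestd <= contact_tol_mm),
              " node(s); assigned to lexicographically first body")
    }
    hit <- bestd <= contact_tol_mm
    state[hit] <- nm[ord][best[hit]]
  }
  line$contact_state <- state
  line$length_mm <- polyline_length(line$nodes)
  line
}

#' Find the departure point and line of action
#'
#' The departure point is the final (highest-index, i.e. nearest the
#' insertion) node contacting the target body; the line-of-action unit vector
#' points along the segment leaving the departure point toward the origin
#' side — the direction the muscle pulls on the bone. If no node contacts the
#' target body, the insertion node is used, the unit vector points along the
#' last segment toward the origin, and a `no_contact` flag is set.
#'
#' @param line a `muscle_line` with populated contact states.
#' @param target_body body name (e.g. the humerus) whose last contact defines
#'   the departure.
#' @param direction search direction; only `"from_insertion"` is defined.
#' @return The line with `departure_index`, `departure_point`,
#'   `departure_uvec` (and possibly a `no_contact` flag) set.
#' @export
find_departure <- function(line, target_body, direction = "from_insertion") {
  direction <- match.arg(direction, "from_insertion")
  n <- nrow(line$nodes)
  idx <- which(line$contact_state == target_body)
  if (length(idx) == 0L) {
    line$departure_index <- n
    line$departure_point <- line$nodes[n, ]
    line$departure_uvec <- unit3(line$nodes[n - 1L, ] - line$nodes[n, ])
    line$flags <- union(line$flags, "no_contact")
  } else {
    i <- max(idx)
    line$departure_index <- i
    line$departure_point <- line$nodes[i, ]
    j <- if (i > 1L) i - 1L else i + 1L
    u <- line$nodes[j, ] - line$nodes[i, ]
    if (i == 1L) u <- -u
    line$departure_uvec <- unit3(u)
  }
  line
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize zero vector")
  v / n
}
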