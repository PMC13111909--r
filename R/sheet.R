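#' Sheet material parameters
#'
#' The sheet is a numerical device — a compliant, deformable surface that
#' guides muscle lines — not a constitutive model of muscle tissue. Young's
#' modulus scales all spring stiffnesses; a Poisson ratio of 0 matches the
#' uncoupled edge-spring discretization.
#'
#' @param youngs_modulus in MPa (default 1).
#' @param poisson_ratio dimensionless, in `[0, 0.5)`; only 0 is realized by
#'   the spring discretization, other values are rejected.
#' @return An object of class `sheet_material`.
#' @export
sheet_material <- function(youngs_modulus = 1, poisson_ratio = 0) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  if (poisson_ratio != 0) {
    stop("the edge-spring membrane realizes poisson_ratio = 0 only")
  }
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio),
            class = "sheet_material")
}

#' Geodesic curve between two points on a mesh surface
#'
#' Dijkstra shortest path over the mesh edge graph, straightened by iterative
#' on-surface smoothing (each interior point moves toward the average of its
#' neighbours and is re-projected onto the surface), then resampled to
#' `subdivisions + 1` points at uniform arc length.
#'
#' @param mesh a [trimesh].
#' @param start,end points within `surface_tol` of the surface.
#' @param subdivisions number of curve subdivisions (default 50).
#' @param surface_tol how far off the surface the end points may be (mm).
#' @return A `(subdivisions + 1) x 3` matrix of on-surface points (a single
#'   row, with a warning, when start and end coincide).
#' @export
geodesic_curve <- function(mesh, start, end, subdivisions = 50,
                           surface_tol = 0.5) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  h <- mesh_handle(mesh)
  inv <- solve(h$pose)
  to_base <- function(p) apply_transform(inv, p)
  to_world <- function(p) apply_transform(h$pose, p)
  q <- mesh_query(mesh, rbind(start, end))
  if (any(abs(q$sdist) > surface_tol)) {
    stop("geodesic end point is ", signif(max(abs(q$sdist)), 3),
         " mm off the surface (tolerance ", surface_tol, ")")
  }
  ps <- q$closest[1, ]
  pe <- q$closest[2, ]
  if (sqrt(sum((ps - pe)^2)) < 1e-9) {
    warning("degenerate geodesic: start and end coincide")
    return(matrix(ps, nrow = 1))
  }
  # Dijkstra over the mesh edge graph, with the projected end points tied
  # into the vertices of their containing faces.
  f <- mesh$faces
  v <- mesh$vertices
  edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1L, sort)))
  elen <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] - v[edges[, 2], , drop = FALSE])^2))
  nv <- nrow(v)
  sid <- nv + 1L
  eid <- nv + 2L
  fs <- f[q$face[1], ]
  fe <- f[q$face[2], ]
  extra <- rbind(cbind(sid, fs), cbind(eid, fe))
  exlen <- c(
    sqrt(colSums((t(v[fs, , drop = FALSE]) - ps)^2)),
    sqrt(colSums((t(v[fe, , drop = FALSE]) - pe)^2))
  )
  g <- igraph::make_graph(t(rbind(edges, extra)), n = nv + 2L, directed = FALSE)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = sid, to = eid, weights = c(elen, exlen),
                           output = "vpath")
  )
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2L) stop("disconnected surface components: no geodesic path")
  inner <- vp[vp <= nv]
  path <- rbind(ps, v[inner, , drop = FALSE], pe)
  # densify, straighten on the surface, then resample uniformly
  dense <- resample_polyline(path, max(4L * subdivisions, nrow(path)))
  dense <- to_base(dense)
  scale <- sum(sqrt(rowSums((dense[-1, ] - dense[-nrow(dense), ])^2)))
  dense <- .mw_surface_smooth(dense, h$ptr, 5000L, 1e-7 * max(scale, 1))
  out <- resample_polyline(to_world(dense), subdivisions + 1L)
  # resampling interpolates chords; snap back onto the surface
  snapped <- .mw_mesh_project(h$ptr, to_base(out))$closest
  res <- to_world(snapped)
  res[1, ] <- ps
  res[nrow(res), ] <- pe
  res
}

resample_polyline <- function(pts, n_out) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- c(TRUE, seg > 1e-14)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  target <- seq(0, total, length.out = n_out)
  cbind(
    approx(s, pts[, 1], xout = target)$y,
    approx(s, pts[, 2], xout = target)$y,
    approx(s, pts[, 3], xout = target)$y
  )
}

#' Loft curves into a constraining sheet
#'
#' Lofts `length(curves)` lanes (5 in the reference construction) of equal
#' point count into a structured triangulated strip: a grid of
#' `lanes x samples` vertices and `2 (lanes-1) (samples-1)` triangles. The
#' first and last sample columns can be attached to named bodies; attached
#' nodes follow those bodies during [relax_sheet]. Rest spring lengths are
#' pre-scaled by `pretension_scale` to emulate pre-tensioning by shrinking
#' the sheet before pulling its edges to their targets.
#'
#' @param curves list of polylines (matrices with identical row counts),
#'   ordered origin to insertion and laterally consistent.
#' @param attach optional `list(start = body_name, end = body_name)`;
#'   attachment local points are the rest positions (bodies are assumed to be
#'   in their reference pose when the sheet is built).
#' @param material a [sheet_material].
#' @param pretension_scale rest-length scale in `(0, 1]`.
#' @param thickness effective membrane thickness (mm) used in the stiffness
#'   scaling.
#' @return An object of class `sheet`.
#' @export
loft_sheet <- function(curves, attach = NULL, material = sheet_material(),
                       pretension_scale = 0.95, thickness = 1) {
  stopifnot(length(curves) >= 2L, pretension_scale > 0, pretension_scale <= 1)
  ns <- vapply(curves, nrow, 1L)
  if (length(unique(ns)) != 1L) {
    stop("mismatched curve point counts: ", paste(ns, collapse = ", "))
  }
  L <- length(curves)
  S <- ns[1]
  id <- function(l, s) (s - 1L) * L + l
  verts <- matrix(0, L * S, 3)
  for (l in seq_len(L)) for (s in seq_len(S)) verts[id(l, s), ] <- curves[[l]][s, ]
  faces <- matrix(0L, 2L * (L - 1L) * (S - 1L), 3L)
  k <- 1L
  for (l in seq_len(L - 1L)) {
    for (s in seq_len(S - 1L)) {
      a <- id(l, s); b <- id(l + 1L, s); cc <- id(l + 1L, s + 1L); d <- id(l, s + 1L)
      faces[k, ] <- c(a, b, cc)
      faces[k + 1L, ] <- c(a, cc, d)
      k <- k + 2L
    }
  }
  rest <- trimesh(verts, faces, "sheet")
  springs <- build_sheet_springs(verts, L, S, material, thickness, pretension_scale)
  attachments <- NULL
  if (!is.null(attach)) {
    nodes <- c(vapply(seq_len(L), function(l) id(l, 1L), 1L),
               vapply(seq_len(L), function(l) id(l, S), 1L))
    bodies <- rep(c(attach$start, attach$end), each = L)
    attachments <- data.frame(node = nodes, body = bodies,
                              lx = verts[nodes, 1], ly = verts[nodes, 2],
                              lz = verts[nodes, 3], stringsAsFactors = FALSE)
  }
  structure(
    list(rest_mesh = rest, deformed = verts, n_lanes = L, n_samples = S,
         springs = springs, boundary_attachments = attachments,
         material = material, pretension_scale = pretension_scale,
         thickness = thickness, flags = character(0), relaxed = FALSE,
         energy_trace = NULL, max_penetration = NA_real_),
    class = "sheet"
  )
}

# structural (lane + cross) springs and shear diagonals; stiffness
# k = E * thickness * tributary_width / rest_length
build_sheet_springs <- function(verts, L, S, material, thickness, pretension_scale) {
  id <- function(l, s) (s - 1L) * L + l
  dseg <- function(i, j) sqrt(rowSums((verts[i, , drop = FALSE] - verts[j, , drop = FALSE])^2))
  # mean spacings for tributary widths
  li <- unlist(lapply(seq_len(L), function(l) id(l, seq_len(S - 1L))))
  lj <- unlist(lapply(seq_len(L), function(l) id(l, seq_len(S - 1L) + 1L)))
  ti <- unlist(lapply(seq_len(L - 1L), function(l) id(l, seq_len(S))))
  tj <- unlist(lapply(seq_len(L - 1L), function(l) id(l + 1L, seq_len(S))))
  w_trans <- mean(dseg(ti, tj))  # lane spacing
  w_long <- mean(dseg(li, lj))   # sample spacing
  lane_w <- function(l) if (l == 1L || l == L) w_trans / 2 else w_trans
  col_w <- function(s) if (s == 1L || s == S) w_long / 2 else w_long
  E <- material$youngs_modulus
  rows <- list()
  add <- function(i, j, width, kscale = 1) {
    l0 <- dseg(i, j)
    rows[[length(rows) + 1L]] <<- data.frame(
      i = i, j = j, l0 = pretension_scale * l0,
      k = kscale * E * thickness * width / pmax(l0, 1e-9)
    )
  }
  for (l in seq_len(L)) add(id(l, seq_len(S - 1L)), id(l, seq_len(S - 1L) + 1L), lane_w(l))
  for (s in seq_len(S)) add(id(seq_len(L - 1L), s), id(seq_len(L - 1L) + 1L, s), col_w(s))
  for (l in seq_len(L - 1L)) {
    ss <- seq_len(S - 1L)
    add(id(l, ss), id(l + 1L, ss + 1L), sqrt(w_trans * w_long) / 2, kscale = 0.5)
    add(id(l + 1L, ss), id(l, ss + 1L), sqrt(w_trans * w_long) / 2, kscale = 0.5)
  }
  do.call(rbind, rows)
}

#' @export
print.sheet <- function(x, ...) {
  cat(sprintf(
    "sheet: %d x %d grid, %d triangles, %d springs%s%s\n",
    x$n_lanes, x$n_samples, nrow(x$rest_mesh$faces), nrow(x$springs),
    if (x$relaxed) ", relaxed" else "",
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]") else ""
  ))
  invisible(x)
}

#' Sheet solver parameters
#'
#' @param max_iterations iteration cap per load step.
#' @param tol convergence tolerance on the per-node step size (mm).
#' @param contact_stiffness_scale penalty stiffness as a multiple of the mean
#'   spring stiffness.
#' @param ramp_steps number of load steps over which the contact penalty is
#'   ramped on a cold start.
#' @return A list of solver parameters.
#' @export
sheet_solver_params <- function(max_iterations = 300, tol = 1e-6,
                                contact_stiffness_scale = 100, ramp_steps = 5) {
  list(max_iterations = as.integer(max_iterations), tol = tol,
       contact_stiffness_scale = contact_stiffness_scale,
       ramp_steps = as.integer(ramp_steps))
}

#' Relax a sheet to quasi-static equilibrium
#'
#' Minimizes the membrane energy (edge springs at their pre-tensioned rest
#' lengths) plus a quadratic penalty on penetration into the obstacles, with
#' the attached boundary nodes pinned to their bodies' current poses. The
#' minimizer is Newton-type: search directions come from the constant spring
#' stiffness matrix augmented with the contact penalty on the currently
#' penetrating nodes (refactorized only when the active set changes), damped
#' by a backtracking line search so the stored energy trace is
#' non-increasing. On a cold start the contact penalty is ramped over
#' `ramp_steps` load steps; warm restarts (successive frames) solve at full
#' stiffness directly.
#'
#' @param sheet a [sheet].
#' @param obstacles list of posed [trimesh] obstacles the sheet must not
#'   penetrate.
#' @param poses named list of 4x4 transforms (reference to world) for the
#'   attachment bodies; missing bodies are static.
#' @param params a [sheet_solver_params] list.
#' @return The sheet with `deformed` positions, `energy_trace`,
#'   `max_penetration` and (if the iteration cap was hit) an `unconverged`
#'   flag updated.
#' @export
relax_sheet <- function(sheet, obstacles, poses = list(),
                        params = sheet_solver_params()) {
  n <- nrow(sheet$deformed)
  fixed <- logical(n)
  pos <- sheet$deformed
  if (!is.null(sheet$boundary_attachments)) {
    ba <- sheet$boundary_attachments
    fixed[ba$node] <- TRUE
    pos[ba$node, ] <- t(vapply(seq_len(nrow(ba)), function(r) {
      T <- poses[[ba$body[r]]] %||% diag(4)
      drop(apply_transform(T, c(ba$lx[r], ba$ly[r], ba$lz[r])))
    }, numeric(3)))
  }
  free <- which(!fixed)
  dofs <- rep(3L * (free - 1L), each = 3L) + 1:3
  sp <- sheet$springs
  kc <- params$contact_stiffness_scale * mean(sp$k)
  obs <- pack_obstacles(obstacles)
  kci <- kc
  energy <- function(p, hessian = FALSE) {
    .mw_sheet_energy(p, sp$i, sp$j, sp$l0, sp$k, obs, kci, hessian)
  }
  stages <- if (sheet$relaxed) 1 else seq_len(params$ramp_steps) / params$ramp_steps
  converged <- FALSE
  for (stage in stages) {
    kci <- kc * stage
    en <- energy(pos, hessian = TRUE)
    trace <- en$energy
    converged <- FALSE
    for (it in seq_len(params$max_iterations)) {
      H <- Matrix::sparseMatrix(i = en$hi, j = en$hj, x = en$hv,
                                dims = c(3L * n, 3L * n))
      Hff <- Matrix::forceSymmetric(H[dofs, dofs, drop = FALSE], "U")
      gvec <- as.vector(t(en$grad))[dofs]
      mu <- 1e-7 * max(1, max(Matrix::diag(Hff)))
      P <- NULL
      for (try in 1:6) {
        P <- tryCatch(
          as.vector(Matrix::solve(Hff + mu * Matrix::Diagonal(length(dofs)), gvec)),
          error = function(e) NULL
        )
        if (!is.null(P) && all(is.finite(P))) break
        mu <- mu * 100
      }
      if (is.null(P)) stop("sheet Hessian solve failed")
      stepmax <- max(abs(P))
      if (stepmax < params$tol) { converged <- TRUE; break }
      if (stepmax > 10) P <- P * (10 / stepmax) # trust-region style cap (mm)
      Pm <- matrix(P, ncol = 3, byrow = TRUE)
      alpha <- 1
      improved <- FALSE
      for (bt in 1:30) {
        trial <- pos
        trial[free, ] <- pos[free, ] - alpha * Pm
        en2 <- energy(trial, hessian = TRUE)
        if (en2$energy <= en$energy) { improved <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!improved) { converged <- TRUE; break } # at the numerical floor
      if (max(abs(alpha * Pm)) < params$tol) converged <- TRUE
      pos <- trial
      en <- en2
      trace <- c(trace, en$energy)
      if (converged) break
    }
  }
  sheet$deformed <- pos
  sheet$energy_trace <- trace
  sheet$max_penetration <- en$max_penetration
  sheet$relaxed <- TRUE
  if (!converged) {
    sheet$flags <- union(sheet$flags, "unconverged")
    warning("relax_sheet unconverged after ", params$max_iterations, " iterations")
  }
  sheet
}

#' Sheet surface as a mesh
#'
#' @param sheet a [sheet].
#' @param deformed use the deformed (default) or rest positions.
#' @param body_name body name for the exported mesh.
#' @return A [trimesh] (e.g. for [write_stl]).
#' @export
sheet_as_trimesh <- function(sheet, deformed = TRUE, body_name = "sheet") {
  v <- if (deformed) sheet$deformed else sheet$rest_mesh$vertices
  trimesh(v, sheet$rest_mesh$faces, body_name)
}

#' Bind a muscle line to a sheet
#'
#' Computes, once, the closest-point projection of every line node onto the
#' sheet's rest surface and stores it as barycentric coordinates. The bound
#' line then follows the sheet's motion: at any frame its nodes are the
#' deformed-sheet positions of those material points.
#'
#' @param line a `muscle_line` (typically the reference-frame wrap).
#' @param sheet a [sheet].
#' @return An object of class `sheet_binding`.
#' @export
bind_line_to_sheet <- function(line, sheet) {
  h <- mesh_handle(sheet$rest_mesh)
  pr <- .mw_mesh_project(h$ptr, line$nodes)
  structure(list(face = pr$face, bary = pr$bary, name = line$name,
                 params = line$params),
            class = "sheet_binding")
}

#' Constrain a muscle line to a (deformed) sheet
#'
#' Each node is replaced by its material point on the sheet: the closest
#' point projection onto the sheet is computed once (on the rest shape,
#' unless a binding is supplied) and the projected points follow the sheet's
#' deformation. Contact states and the departure point are re-derived on the
#' constrained line when obstacles are given.
#'
#' @param line a `muscle_line`.
#' @param sheet a relaxed [sheet].
#' @param binding optional [bind_line_to_sheet] result to reuse across frames.
#' @param obstacles optional list of posed [trimesh] obstacles for contact
#'   re-classification.
#' @param target_body optional body name for [find_departure].
#' @return The constrained `muscle_line` (nodes on the deformed sheet).
#' @export
constrain_line_to_sheet <- function(line, sheet, binding = NULL,
                                    obstacles = NULL, target_body = NULL) {
  if (is.null(binding)) binding <- bind_line_to_sheet(line, sheet)
  fv <- sheet$rest_mesh$faces[binding$face, , drop = FALSE]
  d <- sheet$deformed
  nodes <- binding$bary[, 1] * d[fv[, 1], , drop = FALSE] +
    binding$bary[, 2] * d[fv[, 2], , drop = FALSE] +
    binding$bary[, 3] * d[fv[, 3], , drop = FALSE]
  out <- new_muscle_line(line$name, nodes, line$params)
  out$flags <- union(line$flags, intersect(sheet$flags, "unconverged"))
  if (!is.null(obstacles)) {
    out <- classify_contacts(out, obstacles, line$params$contact_tol_mm)
    if (!is.null(target_body)) out <- find_departure(out, target_body)
  }
  out
}

#' Detect sheet buckling
#'
#' Flags triangles whose deformed normal deviates by more than 90 degrees
#' from the area-weighted average normal of their vertex-adjacent neighbours
#' (folds), and triangles involved in self-intersections.
#'
#' @param sheet a [sheet] (deformed state) or a [trimesh].
#' @return Sorted integer vector of flagged triangle indices, with attributes
#'   `folded` and `self_intersecting` giving each subset.
#' @export
detect_buckling <- function(sheet) {
  mesh <- if (inherits(sheet, "sheet")) sheet_as_trimesh(sheet) else sheet
  v <- mesh$vertices
  f <- mesh$faces
  nf <- nrow(f)
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  ) # area-weighted (unnormalized) face normals
  # neighbourhood sums per vertex, then per face excluding itself
  vsum <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c3 in 1:3) {
      vsum[, c3] <- vsum[, c3] + unname(tapply(
        n[, c3], factor(f[, k], levels = seq_len(nrow(v))), sum, default = 0
      ))
    }
  }
  folded <- logical(nf)
  for (t in seq_len(nf)) {
    vv <- unique(f[t, ])
    field <- colSums(vsum[vv, , drop = FALSE]) - 3 * n[t, ]
    folded[t] <- sum(field * n[t, ]) < 0
  }
  selfx <- .mw_self_intersect(v, f)
  flagged <- sort(unique(c(which(folded), which(selfx))))
  attr(flagged, "folded") <- which(folded)
  attr(flagged, "self_intersecting") <- which(selfx)
  flagged
}

#' Total surface area of a mesh
#'
#' @param mesh a [trimesh].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(tri_areas2(mesh$vertices, mesh$faces)) / 2
}
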