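#' Triangle surface mesh of one rigid body
#'
#' A `trimesh` is the package's mesh container: an `n x 3` vertex matrix (mm),
#' an `m x 3` integer face matrix (1-based vertex indices, counter-clockwise
#' winding seen from outside), and a body name. Proximity queries against the
#' mesh are accelerated by a compiled spatial index that is built lazily and
#' cached on the object.
#'
#' @param vertices numeric matrix, one vertex per row, in mm.
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param body_name identifier of the rigid body this surface belongs to.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, body_name = "body") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stop("empty mesh")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  m <- structure(
    list(vertices = vertices, faces = faces, body_name = as.character(body_name)),
    class = "trimesh"
  )
  attr(m, "handle") <- new_mesh_handle()
  m
}

new_mesh_handle <- function(ptr = NULL, pose = diag(4)) {
  e <- new.env(parent = emptyenv())
  e$ptr <- ptr
  e$pose <- pose
  e
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf(
    "trimesh '%s': %d vertices, %d faces\n",
    x$body_name, nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

# Return list(ptr, pose) for compiled queries. The compiled index stores the
# coordinates the mesh had when the index was built; `pose` maps those onto
# the mesh's current vertices (identity unless the mesh came from pose_body).
mesh_handle <- function(mesh) {
  h <- attr(mesh, "handle")
  if (is.null(h) || is.null(h$ptr) || !.mw_xptr_valid(h$ptr)) {
    ptr <- .mw_mesh_build(mesh$vertices, mesh$faces)
    if (is.null(h)) {
      # object predates handle support (e.g. deserialized); can't cache
      return(list(ptr = ptr, pose = diag(4)))
    }
    h$ptr <- ptr
    h$pose <- diag(4)
  }
  list(ptr = h$ptr, pose = h$pose)
}

#' Signed distance and closest-point query against a mesh
#'
#' Signed distance is positive outside the surface; the sign comes from the
#' angle-weighted pseudo-normal of the nearest surface feature, so it is
#' meaningful for closed meshes and for open meshes interpreted as oriented
#' surfaces.
#'
#' @param mesh a [trimesh].
#' @param points numeric matrix of query points (world coordinates), one per row.
#' @return A list with `sdist` (signed distances, mm), `closest` (closest
#'   surface points), `normal` (outward direction at the closest feature) and
#'   `face` (1-based nearest face index).
#' @export
mesh_query <- function(mesh, points) {
  points <- rbind3(points)
  h <- mesh_handle(mesh)
  .mw_mesh_query(h$ptr, points, h$pose)
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

# obstacle packing for the compiled solvers
pack_obstacles <- function(obstacles) {
  lapply(obstacles, function(m) {
    h <- mesh_handle(m)
    list(ptr = h$ptr, pose = h$pose)
  })
}

#' Weld duplicate vertices
#'
#' Merges vertices that agree within `tol` (mm) and drops degenerate
#' (zero-area) triangles. STL files store each facet's vertices independently,
#' so welding is applied on read.
#'
#' @param mesh a [trimesh].
#' @param tol welding tolerance in mm.
#' @return A `trimesh` with deduplicated vertices; face winding is preserved.
#' @export
mesh_weld <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  area2 <- tri_areas2(newv, f)
  f <- f[area2 > (tol * tol), , drop = FALSE]
  if (nrow(f) == 0L) stop("empty mesh after welding")
  trimesh(newv, f, mesh$body_name)
}

tri_areas2 <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2)
}

#' Concatenate meshes into one body surface
#'
#' @param ... `trimesh` objects.
#' @param body_name name of the combined body.
#' @return A single `trimesh`.
#' @export
mesh_merge <- function(..., body_name = "body") {
  parts <- list(...)
  v <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$vertices), 1L)))
  f <- do.call(rbind, Map(function(p, o) p$faces + o, parts, offs[-length(offs)]))
  trimesh(v, f, body_name)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with all vertices projected onto the sphere. At
#' subdivision level `k` the maximum chordal sag of a face below the sphere is
#' approximately `r * (1 - cos(a))` with `a` the face circumradius angle
#' (about 0.024 mm at level 4 and 0.006 mm at level 5 for r = 30 mm).
#'
#' @param radius sphere radius (mm).
#' @param center sphere centre.
#' @param subdivisions number of 4-to-1 triangle subdivisions of the icosahedron.
#' @param body_name body identifier.
#' @return A `trimesh`.
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3,
                           body_name = "sphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ekey <- character(0)
    emid <- integer(0)
    midpoint <- function(i, j) {
      key <- if (i < j) paste(i, j) else paste(j, i)
      k <- match(key, ekey)
      if (!is.na(k)) return(emid[k])
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      ekey <<- c(ekey, key)
      emid <<- c(emid, nrow(v))
      nrow(v)
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(c3, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2, center, `+`)
  trimesh(v, f, body_name)
}

#' Axis-aligned box mesh
#'
#' @param center box centre.
#' @param dims box extents (mm) along x, y, z.
#' @param body_name body identifier.
#' @return A closed 12-triangle `trimesh` with outward winding.
#' @export
mesh_box <- function(center = c(0, 0, 0), dims = c(1, 1, 1), body_name = "box") {
  h <- dims / 2
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(sgn, 2, h, `*`), 2, center, `+`)
  # vertex order: (x,y,z) signs as expand.grid: 1=(---),2=(+--),3=(-+-),4=(++-),
  # 5=(--+),6=(+-+),7=(-++),8=(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z-
    c(5, 6, 8), c(5, 8, 7),   # z+
    c(1, 2, 6), c(1, 6, 5),   # y-
    c(3, 7, 8), c(3, 8, 4),   # y+
    c(1, 5, 7), c(1, 7, 3),   # x-
    c(2, 4, 8), c(2, 8, 6)    # x+
  )
  trimesh(v, f, body_name)
}

#' Closed cylinder mesh
#'
#' @param radius cylinder radius (mm).
#' @param p0,p1 axis end points.
#' @param n_circ number of vertices around the circumference.
#' @param n_axial number of segments along the axis.
#' @param body_name body identifier.
#' @return A closed `trimesh` with capped ends.
#' @export
mesh_cylinder <- function(radius, p0, p1, n_circ = 32, n_axial = 4,
                          body_name = "cylinder") {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("degenerate cylinder axis")
  w <- axis / len
  u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * w) * w
  u <- u / sqrt(sum(u^2))
  vv <- c(
    w[2] * u[3] - w[3] * u[2],
    w[3] * u[1] - w[1] * u[3],
    w[1] * u[2] - w[2] * u[1]
  )
  ang <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  rings <- lapply(0:n_axial, function(k) {
    cpt <- p0 + axis * (k / n_axial)
    t(vapply(
      ang,
      function(a) cpt + radius * (cos(a) * u + sin(a) * vv),
      numeric(3)
    ))
  })
  v <- do.call(rbind, rings)
  f <- NULL
  for (k in 0:(n_axial - 1)) {
    o1 <- k * n_circ
    o2 <- (k + 1) * n_circ
    for (i in seq_len(n_circ)) {
      j <- i %% n_circ + 1L
      f <- rbind(f, c(o1 + i, o1 + j, o2 + j), c(o1 + i, o2 + j, o2 + i))
    }
  }
  c0 <- nrow(v) + 1L
  v <- rbind(v, p0, p1)
  c1 <- nrow(v)
  for (i in seq_len(n_circ)) {
    j <- i %% n_circ + 1L
    f <- rbind(f, c(c0, j, i))                                   # bottom cap
    f <- rbind(f, c(c1, n_axial * n_circ + i, n_axial * n_circ + j)) # top cap
  }
  trimesh(v, f, body_name)
}
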