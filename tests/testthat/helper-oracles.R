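# Independent oracles, kept free of the package's own closed-form code paths.

# Brute-force shortest path around a circle in a plane: parameterize the path
# as straight segment -> arc(phi1..phi2) -> straight segment and minimize the
# total length numerically over the two arc end angles (no tangency
# assumption).
brute_circle_wrap_length <- function(origin, insertion, center, radius, normal) {
  nrm <- normal / sqrt(sum(normal^2))
  e1 <- origin - center
  e1 <- e1 - sum(e1 * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    nrm[2] * e1[3] - nrm[3] * e1[2],
    nrm[3] * e1[1] - nrm[1] * e1[3],
    nrm[1] * e1[2] - nrm[2] * e1[1]
  )
  p2 <- function(p) c(sum((p - center) * e1), sum((p - center) * e2))
  O <- p2(origin)
  I <- p2(insertion)
  seg_clearance <- function(a, b) {
    # distance of the segment ab from the circle centre (the 2D origin)
    d <- b - a
    t <- min(max(-sum(a * d) / sum(d * d), 0), 1)
    sqrt(sum((a + t * d)^2))
  }
  len <- function(par) {
    a <- radius * c(cos(par[1]), sin(par[1]))
    b <- radius * c(cos(par[2]), sin(par[2]))
    arc <- abs(par[2] - par[1]) * radius
    pen <- pmax(0, radius - c(seg_clearance(O, a), seg_clearance(b, I)))
    sqrt(sum((a - O)^2)) + arc + sqrt(sum((b - I)^2)) + 1e4 * sum(pen)
  }
  psi <- atan2(I[2], I[1])
  fit <- optim(c(psi * 0.25, psi * 0.75), len, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 20000))
  fit$value
}

# Dense surface-graph shortest-path upper bound: vertices of the obstacle
# mesh plus the two end points, connected by every segment that does not
# penetrate the mesh.
graph_path_length <- function(mesh, origin, insertion, clearance = 1e-6) {
  v <- rbind(mesh$vertices, origin, insertion)
  n <- nrow(v)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  keep <- logical(length(pair_i))
  tt <- seq(0.05, 0.95, length.out = 9)
  for (e in seq_along(pair_i)) {
    a <- v[pair_i[e], ]
    b <- v[pair_j[e], ]
    pts <- outer(1 - tt, a) + outer(tt, b)
    keep[e] <- all(mesh_query(mesh, pts)$sdist > -clearance)
  }
  pi1 <- pair_i[keep]
  pj1 <- pair_j[keep]
  w <- sqrt(rowSums((v[pi1, , drop = FALSE] - v[pj1, , drop = FALSE])^2))
  g <- igraph::make_graph(rbind(pi1, pj1), n = n, directed = FALSE)
  as.numeric(igraph::distances(g, v = n - 1, to = n, weights = w))
}
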