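#' Closed-form wrap of a line around a circle (sphere cross-section)
#'
#' Tangent geometry of the shortest path from `origin` to `insertion` around
#' the circle of radius `radius` centred at `center` in the plane through
#' `center` with normal `normal`. Both end points must lie in that plane.
#' When the straight chord misses the circle the path is the chord itself.
#' Used as the analytic oracle for sphere wrapping: for a sphere, the
#' shortest wrapped path lies in the plane of the end points and the sphere
#' centre, and a sheet-guided line is modelled by the lane plane at its
#' offset along the rotation axis.
#'
#' @param origin,insertion end points (mm), in the plane.
#' @param center circle centre (mm).
#' @param radius circle radius (mm); both end points must be outside.
#' @param normal plane normal (unit not required).
#' @return A list: `penetrates` (does the chord hit the circle), `length`
#'   (path length, mm), `departure` (tangent point nearest the insertion),
#'   `uvec` (unit direction at the departure toward the origin side),
#'   `arc_angle` (wrapped arc, radians).
#' @export
circle_wrap <- function(origin, insertion, center, radius, normal) {
  nrm <- unit3(as.numeric(normal))
  O <- as.numeric(origin) - as.numeric(center)
  I <- as.numeric(insertion) - as.numeric(center)
  if (abs(sum(O * nrm)) > 1e-6 * max(1, sqrt(sum(O^2))) ||
      abs(sum(I * nrm)) > 1e-6 * max(1, sqrt(sum(I^2)))) {
    stop("end points do not lie in the wrap plane")
  }
  e1 <- unit3(O)
  e2 <- cross3(nrm, e1)
  dO <- sqrt(sum(O^2))
  dI <- sqrt(sum(I^2))
  if (dO <= radius || dI <= radius) stop("end point inside the circle")
  psi <- atan2(sum(I * e2), sum(I * e1))
  s <- if (psi >= 0) 1 else -1
  aO <- acos(radius / dO)
  aI <- acos(radius / dI)
  arc <- abs(psi) - aO - aI
  if (arc <= 0) {
    u <- unit3(as.numeric(origin) - as.numeric(insertion))
    return(list(penetrates = FALSE,
                length = sqrt(sum((O - I)^2)),
                departure = as.numeric(insertion),
                uvec = u, arc_angle = 0))
  }
  phiT <- s * (abs(psi) - aI)
  p <- as.numeric(center) + radius * (cos(phiT) * e1 + sin(phiT) * e2)
  u <- s * (sin(phiT) * e1 - cos(phiT) * e2)
  list(penetrates = TRUE,
       length = sqrt(dO^2 - radius^2) + sqrt(dI^2 - radius^2) + radius * arc,
       departure = p,
       uvec = unit3(u),
       arc_angle = arc)
}

#' Analytic sphere-wrap of a muscle line
#'
#' Shortest path around a sphere between two external points: straight
#' tangent segments joined by a great-circle arc, all lying in the plane of
#' the end points and the sphere centre.
#'
#' @param origin,insertion end points (mm), outside the sphere.
#' @param center sphere centre.
#' @param radius sphere radius (mm).
#' @return As [circle_wrap], computed in the end-point/centre plane.
#' @export
sphere_wrap_analytic <- function(origin, insertion, center, radius) {
  O <- as.numeric(origin) - as.numeric(center)
  I <- as.numeric(insertion) - as.numeric(center)
  n <- cross3(O, I)
  if (sqrt(sum(n^2)) < 1e-9 * sqrt(sum(O^2)) * sqrt(sum(I^2))) {
    stop("end points and centre are collinear; the wrap plane is undefined")
  }
  circle_wrap(origin, insertion, center, radius, n)
}
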