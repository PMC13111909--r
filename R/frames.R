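#' Anatomic coordinate system
#'
#' Orthonormal right-handed triad (`x cross y = z`) with an origin, stored as
#' unit row vectors.
#'
#' @param origin origin point (mm).
#' @param x_axis,y_axis,z_axis unit axis vectors.
#' @return An object of class `coordinate_system`.
#' @export
coordinate_system <- function(origin, x_axis, y_axis, z_axis) {
  A <- rbind(x = x_axis, y = y_axis, z = z_axis)
  if (max(abs(A %*% t(A) - diag(3))) > 1e-9) stop("axes not orthonormal")
  if (max(abs(cross3(x_axis, y_axis) - z_axis)) > 1e-9) {
    stop("axes not right-handed (x cross y != z)")
  }
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "coordinate_system")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.coordinate_system <- function(x, ...) {
  cat("coordinate_system\n")
  cat("  origin:", sprintf("%.3f", x$origin), "\n")
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(" ", sub("_axis", "", ax), ":", sprintf("%+.4f", x[[ax]]), "\n")
  }
  invisible(x)
}

#' Scapular coordinate system from three landmarks
#'
#' ISB-style construction with the joint-centre origin: the lateral axis
#' `z` points from the trigonum spinae to the glenoid (or glenosphere)
#' centre; `x` is the anterior axis perpendicular to the plane of the three
#' landmarks; `y = z cross x` is superior. The construction is intrinsically
#' sign-safe: `y` points away from the inferior angle and the triad is
#' right-handed for any non-collinear landmark set, including mirrored
#' (left-sided) data — for which the *anatomic* anterior direction is the
#' user's responsibility, since three landmarks cannot reveal the side.
#'
#' @param trigonum trigonum spinae landmark (mm).
#' @param inferior_angle inferior angle landmark (mm).
#' @param center glenoid centre (pre-op) or glenosphere centre (post-op),
#'   used as the origin.
#' @return A [coordinate_system].
#' @export
build_scapular_cs <- function(trigonum, inferior_angle, center) {
  z <- center - trigonum
  if (sqrt(sum(z^2)) < 1e-9) stop("collinear or coincident scapular landmarks")
  z <- unit3(z)
  inplane <- inferior_angle - trigonum
  x <- cross3(z, inplane)
  if (sqrt(sum(x^2)) < 1e-9 * sqrt(sum(inplane^2))) {
    stop("collinear scapular landmarks")
  }
  x <- unit3(x)
  y <- cross3(z, x)
  # y = (z.v) z - v with v = IA - TS, so y always points away from the
  # inferior angle; no sign disambiguation is needed
  coordinate_system(center, x, y, z)
}

#' Least-squares cylinder fit
#'
#' Fits an infinite cylinder to a point cloud by minimizing the radial
#' residuals (distance to axis minus radius, radius profiled out as the mean
#' axial distance). The axis is initialized from the principal direction of
#' greatest extent and refined together with its position by quasi-Newton
#' minimization.
#'
#' @param points matrix of at least 8 points (mm), not coplanar.
#' @return A list of class `cylinder_fit` with `axis_point`,
#'   `axis_direction` (unit), `radius` (mm) and `rms_residual` (mm).
#' @export
fit_cylinder <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 8L) stop("cylinder fit needs at least 8 points")
  ctr <- colMeans(points)
  pc <- prcomp(points, center = TRUE)
  if (pc$sdev[3] < 1e-7 * pc$sdev[1]) stop("degenerate cylinder fit: coplanar points")
  if (pc$sdev[2] < 1e-7 * pc$sdev[1]) stop("degenerate cylinder fit: collinear points")
  d0 <- pc$rotation[, 1]
  # tangent-plane basis for the axis direction parameters
  u <- pc$rotation[, 2]
  w <- pc$rotation[, 3]
  resid <- function(par) {
    d <- unit3(d0 + par[1] * u + par[2] * w)
    p0 <- ctr + par[3] * u + par[4] * w
    rel <- sweep(points, 2, p0)
    ax <- rel %*% d
    rad <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
    rad - mean(rad)
  }
  obj <- function(par) sum(resid(par)^2)
  fit <- optim(c(0, 0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  par <- fit$par
  d <- unit3(d0 + par[1] * u + par[2] * w)
  p0 <- ctr + par[3] * u + par[4] * w
  rel <- sweep(points, 2, p0)
  ax <- rel %*% d
  rad <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
  structure(
    list(axis_point = p0 + mean(ax) * d, axis_direction = d,
         radius = mean(rad),
         rms_residual = sqrt(mean((rad - mean(rad))^2))),
    class = "cylinder_fit"
  )
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "cylinder_fit: radius %.3f mm, axis (%+.4f %+.4f %+.4f), rms residual %.4g mm\n",
    x$radius, x$axis_direction[1], x$axis_direction[2], x$axis_direction[3],
    x$rms_residual
  ))
  invisible(x)
}

#' Humeral coordinate system from head centre, shaft fit and lesser tuberosity
#'
#' `y` is the shaft axis oriented superiorly (from the shaft toward the head
#' centre); `x` is the component of the head-to-lesser-tuberosity direction
#' orthogonal to `y` (the tuberosity "clocks" the anterior axis); and
#' `z = x cross y` completes the right-handed triad.
#'
#' @param head_center humeral head centre (mm), used as origin.
#' @param shaft a [fit_cylinder] result for the humeral shaft.
#' @param lesser_tuberosity lesser tuberosity landmark (mm), off the shaft
#'   axis.
#' @return A [coordinate_system].
#' @export
build_humeral_cs <- function(head_center, shaft, lesser_tuberosity) {
  y <- shaft$axis_direction
  if (sum(y * (head_center - shaft$axis_point)) < 0) y <- -y
  rel <- lesser_tuberosity - head_center
  x <- rel - sum(rel * y) * y
  if (sqrt(sum(x^2)) < 1e-9 * max(sqrt(sum(rel^2)), 1)) {
    stop("lesser tuberosity is collinear with the shaft axis")
  }
  x <- unit3(x)
  coordinate_system(head_center, x, y, cross3(x, y))
}
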