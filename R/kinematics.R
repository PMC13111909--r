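#' Rodrigues rotation as a homogeneous transform
#'
#' Builds the 4x4 transform of a rotation by `angle` about the axis through
#' `pivot` with direction `axis`, using the Rodrigues rotation formula
#' `R = I + sin(a) K + (1 - cos(a)) K^2` with `K` the cross-product matrix of
#' the unit axis. The transform maps the pivot to itself.
#'
#' @param axis rotation axis (length-3, must be non-zero; normalized internally).
#' @param angle rotation angle in radians.
#' @param pivot point on the rotation axis (mm).
#' @return A 4x4 homogeneous transform.
#' @export
rodrigues <- function(axis, angle, pivot = c(0, 0, 0)) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero rotation axis")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- pivot - R %*% pivot
  T
}

motion_transform <- function(motion, frame) {
  if (frame < 1L || frame > length(motion$frames)) {
    stop("frame ", frame, " out of range (motion has ", length(motion$frames), " frames)")
  }
  motion$frames[[frame]]
}

apply_transform <- function(T, points) {
  points <- rbind3(points)
  sweep(points %*% t(T[1:3, 1:3]), 2, T[1:3, 4], `+`)
}

#' Pose a body mesh at a motion frame
#'
#' Vertices are transformed by the frame's rigid transform; topology is
#' unchanged. The mesh's cached spatial index is reused: queries against the
#' posed mesh transform points into the reference frame instead of rebuilding
#' the index.
#'
#' @param mesh the body's [trimesh] in frame-0 coordinates.
#' @param motion the body's [rigid_motion].
#' @param frame 1-based frame index.
#' @return The posed `trimesh`.
#' @export
pose_body <- function(mesh, motion, frame) {
  T <- motion_transform(motion, frame)
  out <- mesh
  out$vertices <- apply_transform(T, mesh$vertices)
  old <- mesh_handle(mesh)
  attr(out, "handle") <- new_mesh_handle(old$ptr, T %*% old$pose)
  out
}

#' Track a probe point through a motion
#'
#' @param probe a [probe].
#' @param motion the [rigid_motion] of the probe's body.
#' @param frame 1-based frame index.
#' @return World-frame position (length-3) at the frame.
#' @export
track_probe <- function(probe, motion, frame) {
  if (!identical(probe$body_name, motion$body_name)) {
    stop("probe '", probe$name, "' belongs to body '", probe$body_name,
         "', not '", motion$body_name, "'")
  }
  drop(apply_transform(motion_transform(motion, frame), probe$local_position))
}
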