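#' Muscle length of a polyline
#'
#' @param line a `muscle_line` (or a node matrix).
#' @return Sum of segment lengths (mm).
#' @export
muscle_length <- function(line) {
  nodes <- if (inherits(line, "muscle_line")) line$nodes else rbind3(line)
  polyline_length(nodes)
}

#' Refine a departure point to perpendicularity
#'
#' Moves the departure point along the line of action to the foot of the
#' perpendicular from the centre of rotation, so the reported moment arm is
#' the shortest distance between the line of action and the joint centre
#' (discretization places the departure node only near, not at, the foot).
#'
#' @param point departure point (mm).
#' @param uvec unit line-of-action vector.
#' @param cor joint centre of rotation (mm).
#' @return The refined point; `(refined - cor)` is orthogonal to `uvec`.
#' @export
refine_departure <- function(point, uvec, cor) {
  point + sum((cor - point) * uvec) * uvec
}

#' Resultant moment arm
#'
#' Shortest perpendicular distance between the muscle's line of action and
#' the joint centre of rotation.
#'
#' @param refined_point departure point refined by [refine_departure].
#' @param uvec unit line-of-action vector.
#' @param cor joint centre of rotation.
#' @return Moment arm in mm (non-negative).
#' @export
resultant_moment_arm <- function(refined_point, uvec, cor) {
  sqrt(sum(cross3(refined_point - cor, uvec)^2))
}

#' Decompose a moment arm about anatomic axes
#'
#' The moment-arm vector is `m = (p - cor) x u`; the component about an axis
#' `a` is `m . a`. Elevation is reported with its sign reversed (by the
#' right-hand rule an elevating muscle's component about the anterior axis is
#' negative; the flip makes elevation positive for ease of interpretation).
#'
#' @param refined_point departure point refined by [refine_departure].
#' @param uvec unit line-of-action vector.
#' @param cor joint centre of rotation.
#' @param axes list with unit vectors `elevation` (scapular anterior axis
#'   X_s), `plane` (scapular superior axis Y_s), `axial` (humeral shaft axis
#'   Y_h).
#' @return Named numeric vector `c(ma_elevation, ma_plane, ma_axial)` in mm.
#' @export
decompose_moment_arm <- function(refined_point, uvec, cor, axes) {
  m <- cross3(refined_point - cor, uvec)
  c(ma_elevation = -sum(m * axes$elevation),
    ma_plane = sum(m * axes$plane),
    ma_axial = sum(m * axes$axial))
}

#' Flag departure-point discontinuities
#'
#' Marks frames where the departure point jumps by more than `jump_tol_mm`
#' between consecutive frames of one muscle's time-ordered records (either in
#' Euclidean distance or in any single coordinate), appending a
#' `departure_jump` token to the `flags` column.
#'
#' @param records time-ordered records for one muscle (data frame with
#'   `departure_x/y/z` and `flags` columns).
#' @param jump_tol_mm per-frame jump tolerance (mm); default 5.
#' @return The records with updated `flags`.
#' @export
flag_discontinuities <- function(records, jump_tol_mm = 5) {
  if (nrow(records) < 2L) return(records)
  dp <- as.matrix(records[, c("departure_x", "departure_y", "departure_z")])
  d <- dp[-1, , drop = FALSE] - dp[-nrow(dp), , drop = FALSE]
  jump <- sqrt(rowSums(d^2)) > jump_tol_mm | apply(abs(d), 1, max) > jump_tol_mm
  jump[is.na(jump)] <- FALSE
  for (k in which(jump)) {
    i <- k + 1L
    toks <- strsplit(records$flags[i], ";", fixed = TRUE)[[1]]
    records$flags[i] <- paste(union(toks[nzchar(toks)], "departure_jump"),
                              collapse = ";")
  }
  records
}
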