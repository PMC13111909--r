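#' Per-frame rigid-body motion
#'
#' Ordered series of 4x4 homogeneous transforms mapping a body's frame-0
#' (reference) coordinates to world coordinates at each frame.
#'
#' @param body_name body identifier.
#' @param frames list of 4x4 homogeneous transforms with orthonormal rotation
#'   blocks (det +1).
#' @param timestamps optional strictly increasing times in seconds.
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(body_name, frames, timestamps = NULL) {
  if (length(frames) < 1L) stop("a rigid_motion needs at least one frame")
  for (k in seq_along(frames)) {
    T <- frames[[k]]
    if (!is.matrix(T) || any(dim(T) != c(4L, 4L))) stop("frame ", k, " is not a 4x4 matrix")
    R <- T[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
      stop("non-orthonormal rotation in frame ", k)
    }
  }
  if (!is.null(timestamps)) {
    if (length(timestamps) != length(frames)) stop("timestamps length mismatch")
    if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  }
  structure(
    list(body_name = as.character(body_name), frames = frames, timestamps = timestamps),
    class = "rigid_motion"
  )
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf(
    "rigid_motion '%s': %d frames%s\n",
    x$body_name, length(x$frames),
    if (is.null(x$timestamps)) "" else sprintf(
      " (%.3f..%.3f s)", x$timestamps[1], x$timestamps[length(x$timestamps)]
    )
  ))
  invisible(x)
}

#' Identity (static body) motion
#'
#' @param body_name body identifier.
#' @param n_frames number of frames.
#' @param timestamps optional times in seconds.
#' @return A `rigid_motion` of identity transforms.
#' @export
static_motion <- function(body_name, n_frames, timestamps = NULL) {
  rigid_motion(body_name, replicate(n_frames, diag(4), simplify = FALSE), timestamps)
}

# nearest orthonormal matrix with det +1 (polar decomposition)
polar_orthonormalize <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  Q
}

#' Read rigid-body kinematics from plain text
#'
#' The dialect is a package convention (the upstream tools name only a
#' generic `*.txt`): one frame per line, whitespace-separated, either 16
#' numbers (a row-major 4x4 homogeneous transform) or 17 numbers (a leading
#' timestamp in seconds followed by the 16), detected from the column count.
#' Rotation blocks within 1e-3 of orthonormal are re-orthonormalized by polar
#' decomposition; anything farther is rejected.
#'
#' @param path file path.
#' @param body_name body the motion belongs to.
#' @return A [rigid_motion].
#' @export
read_kinematics <- function(path, body_name) {
  if (!file.exists(path)) stop("kinematics file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty kinematics file: ", path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(x) suppressWarnings(as.numeric(x)))
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) stop("ragged rows in kinematics file: ", path)
  nc <- ncols[1]
  if (!nc %in% c(16L, 17L)) stop("expected 16 or 17 columns per frame, got ", nc)
  if (any(vapply(rows, anyNA, TRUE))) stop("non-numeric value in kinematics file: ", path)
  has_time <- nc == 17L
  timestamps <- if (has_time) vapply(rows, `[`, 0, 1) else NULL
  frames <- lapply(rows, function(r) {
    T <- matrix(if (has_time) r[-1] else r, 4, 4, byrow = TRUE)
    R <- T[1:3, 1:3]
    err <- max(max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
    if (err > 1e-3) stop("non-orthonormal rotation (deviation ", signif(err, 3), ")")
    if (err > 1e-12) T[1:3, 1:3] <- polar_orthonormalize(R)
    T[4, ] <- c(0, 0, 0, 1)
    T
  })
  rigid_motion(body_name, frames, timestamps)
}

#' Write rigid-body kinematics to plain text
#'
#' Canonical formatting: one frame per line, `%.17g` fields separated by
#' single spaces, so write/read/write round-trips are byte-identical.
#'
#' @param motion a [rigid_motion].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(motion, path) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- vapply(seq_along(motion$frames), function(k) {
    vals <- as.vector(t(motion$frames[[k]]))
    if (!is.null(motion$timestamps)) vals <- c(motion$timestamps[k], vals)
    paste(fmt(vals), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
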