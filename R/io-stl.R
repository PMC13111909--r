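#' Read a stereolithography (STL) file
#'
#' Reads ASCII and binary STL dialects. Facet vertices are welded within
#' `weld_tol` so shared vertices become shared indices; face winding is
#' preserved. Facet normals stored in the file are ignored (they are
#' recomputed from winding wherever needed).
#'
#' @param path file path.
#' @param body_name body identifier for the resulting mesh.
#' @param weld_tol vertex welding tolerance in mm.
#' @return A [trimesh].
#' @export
read_stl <- function(path, body_name = NULL, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  if (is.null(body_name)) body_name <- sub("\\.[sS][tT][lL]$", "", basename(path))
  size <- file.info(path)$size
  if (size < 15) stop("malformed STL (file too short) at byte offset 0: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(84, size))
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (!is_binary && !grepl("^\\s*solid", rawToChar(head84[1:min(20, length(head84))]))) {
    stop("malformed STL at byte offset 0: neither binary layout nor 'solid' header")
  }
  if (is_binary) {
    seek(con, 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    if (ntri == 0) stop("empty mesh: ", path)
    raw <- readBin(con, "raw", n = 50 * ntri)
    if (length(raw) < 50 * ntri) {
      stop("malformed STL at byte offset ", 84 + length(raw), ": truncated facet data")
    }
    keep <- rep(rep(c(TRUE, FALSE), c(48L, 2L)), ntri)
    vals <- readBin(raw[keep], "double", size = 4, n = 12 * ntri, endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)
    verts <- matrix(t(vals[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt)
    flines <- grep("^\\s*facet\\s+normal", txt)
    if (length(vlines) == 0) stop("empty mesh: ", path)
    if (length(vlines) != 3 * length(flines)) {
      bad <- if (length(flines)) flines[length(flines)] else 1L
      off <- sum(nchar(txt[seq_len(bad - 1)], type = "bytes") + 1L)
      stop("malformed STL at byte offset ", off, ": facet/vertex count mismatch")
    }
    parse1 <- function(i) {
      toks <- strsplit(trimws(txt[i]), "\\s+")[[1]]
      x <- suppressWarnings(as.numeric(toks[2:4]))
      if (length(toks) < 4 || anyNA(x)) {
        off <- sum(nchar(txt[seq_len(i - 1)], type = "bytes") + 1L)
        stop("malformed STL at byte offset ", off, ": bad vertex line")
      }
      x
    }
    verts <- t(vapply(vlines, parse1, numeric(3)))
  }
  nf <- nrow(verts) / 3
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  mesh_weld(trimesh(verts, faces, body_name), tol = weld_tol)
}

#' Write a mesh to an STL file
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @param binary write the binary dialect (default ASCII).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[t, ], a[t, ], b[t, ], cc[t, ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * nrow(f) + 2)
    out[1] <- sprintf("solid %s", mesh$body_name)
    k <- 2L
    for (t in seq_len(nrow(f))) {
      out[k] <- sprintf("  facet normal %s %s %s", fmt(n[t, 1]), fmt(n[t, 2]), fmt(n[t, 3]))
      out[k + 1] <- "    outer loop"
      out[k + 2] <- sprintf("      vertex %s %s %s", fmt(a[t, 1]), fmt(a[t, 2]), fmt(a[t, 3]))
      out[k + 3] <- sprintf("      vertex %s %s %s", fmt(b[t, 1]), fmt(b[t, 2]), fmt(b[t, 3]))
      out[k + 4] <- sprintf("      vertex %s %s %s", fmt(cc[t, 1]), fmt(cc[t, 2]), fmt(cc[t, 3]))
      out[k + 5] <- "    endloop"
      out[k + 6] <- "  endfacet"
      k <- k + 7L
    }
    out[k] <- sprintf("endsolid %s", mesh$body_name)
    writeLines(out, path)
  }
  invisible(path)
}
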