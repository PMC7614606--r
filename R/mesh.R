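#' Triangulated membrane patches
#'
#' A membrane patch is a triangulated surface of one membrane (ER or OMM)
#' of one contact site: a list with \code{vertices} (N x 3 numeric matrix,
#' nm) and \code{faces} (M x 3 integer matrix of 1-based vertex indices),
#' class \code{"membrane_patch"}.
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates in nm.
#' @param faces M x 3 integer matrix of vertex indices.
#' @param membrane optional label, e.g. \code{"er"} or \code{"omm"}.
#' @return A \code{membrane_patch}.
#' @export
membrane_patch <- function(vertices, faces, membrane = NA_character_) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) {
    stop_mcsarch("vertices must be an N x 3 matrix", "invalid_input_error")
  }
  check_finite_coords(vertices, "mesh vertices")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop_mcsarch("face indices out of range", "invalid_input_error")
  }
  structure(list(vertices = vertices, faces = faces, membrane = membrane),
            class = "membrane_patch")
}

#' @export
print.membrane_patch <- function(x, ...) {
  cat(sprintf("membrane_patch (%s): %d vertices, %d triangles, area %.1f nm^2\n",
              x$membrane, nrow(x$vertices), nrow(x$faces),
              sum(triangle_areas(x))))
  invisible(x)
}

#' Per-triangle areas of a membrane patch
#'
#' @param mesh a \code{membrane_patch}.
#' @return Numeric vector of triangle areas in nm^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Read and write Wavefront OBJ meshes
#'
#' Minimal OBJ support for triangulated surface patches: only \code{v}
#' (vertex) and \code{f} (triangular face) records are handled, which is
#' all the synthetic membranes and the analyses here require.
#'
#' @param path file path.
#' @param mesh a \code{membrane_patch} (write only).
#' @param membrane label attached on read.
#' @return \code{read_obj}: a \code{membrane_patch}; \code{write_obj}: the
#'   path, invisibly.
#' @export
read_obj <- function(path, membrane = NA_character_) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) {
    stop_mcsarch("OBJ file holds no v/f records", "format_error")
  }
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*$", "", x[2:4]))))
  membrane_patch(verts, faces, membrane = membrane)
}

#' @rdname read_obj
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Local membrane normal by total-least-squares plane fit
#'
#' Fits a plane to all mesh vertices within \code{radius} of the anchor
#' (the smallest principal component of the vertex scatter) and returns
#' its unit normal, with the sign oriented towards \code{towards} (for a
#' bridge, its centre point, i.e. the cytosolic side). If fewer than 3
#' vertices fall within the radius the search widens once to twice the
#' radius before failing.
#'
#' @param mesh a \code{membrane_patch}.
#' @param anchor 3-vector, nm.
#' @param radius neighbourhood radius in nm (default 20, the order of a
#'   bridge footprint).
#' @param towards optional 3-vector the normal should point towards.
#' @return Unit 3-vector with attribute \code{n_vertices_used}.
#' @export
local_normal <- function(mesh, anchor, radius = 20, towards = NULL) {
  check_finite_coords(anchor, "anchor")
  d2 <- colSums((t(mesh$vertices) - anchor)^2)
  sel <- d2 <= radius^2
  if (sum(sel) < 3) sel <- d2 <= (2 * radius)^2
  if (sum(sel) < 3) {
    stop_mcsarch(sprintf(
      "fewer than 3 mesh vertices within %g nm (and 2x widening) of anchor",
      radius), "insufficient_data_error")
  }
  pts <- mesh$vertices[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  ev <- eigen(crossprod(sweep(pts, 2, ctr)), symmetric = TRUE)
  n <- ev$vectors[, 3]
  n <- n / sqrt(sum(n^2))
  if (!is.null(towards) && sum(n * (towards - anchor)) < 0) n <- -n
  attr(n, "n_vertices_used") <- sum(sel)
  n
}
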