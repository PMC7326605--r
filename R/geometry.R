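# Elementary geometric predicates shared by all modules.

#' Signed volume of a tetrahedron
#'
#' `dot(p1 - p0, cross(p2 - p0, p3 - p0)) / 6`; the sign encodes orientation
#' (positive for a right-handed vertex order).  Degenerate (coplanar) inputs
#' return 0.
#'
#' @param p0,p1,p2,p3 numeric length-3 coordinates.
#' @return Signed volume (cubic length units).
#' @export
signed_tet_volume <- function(p0, p1, p2, p3) {
  a <- p1 - p0; b <- p2 - p0; c <- p3 - p0
  (a[1] * (b[2] * c[3] - b[3] * c[2]) +
   a[2] * (b[3] * c[1] - b[1] * c[3]) +
   a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
}

# Vectorised signed volumes for a k x 4 connectivity over `points`.
tet_volumes <- function(points, conn) {
  p0 <- points[conn[, 1], , drop = FALSE]
  a <- points[conn[, 2], , drop = FALSE] - p0
  b <- points[conn[, 3], , drop = FALSE] - p0
  c <- points[conn[, 4], , drop = FALSE] - p0
  rowSums(a * cross3(b, c)) / 6
}

#' Unit normal of a triangle
#'
#' Unit vector along `cross(p1 - p0, p2 - p0)`; the orientation follows the
#' vertex order (counter-clockwise seen from the normal side).
#'
#' @param p0,p1,p2 numeric length-3 coordinates of a non-degenerate triangle.
#' @return Unit length-3 vector.
#' @export
triangle_normal <- function(p0, p1, p2) {
  n <- cross3(rbind(p1 - p0), rbind(p2 - p0))[1, ]
  len <- sqrt(sum(n^2))
  if (len == 0)
    mt_geometry_error("degenerate (zero-area) triangle has no normal")
  n / len
}

# Vectorised (non-unit) triangle normals; degenerate rows come out as zero.
triangle_normals <- function(points, faces, unit = TRUE) {
  p0 <- points[faces[, 1], , drop = FALSE]
  n <- cross3(points[faces[, 2], , drop = FALSE] - p0,
              points[faces[, 3], , drop = FALSE] - p0)
  if (unit) normalize_rows(n) else n
}

#' Volume enclosed by a closed oriented surface
#'
#' Sums the signed volumes of the tetrahedra formed by each face and the
#' origin; for a closed, consistently outward-oriented surface this is the
#' enclosed volume (and is translation-invariant).  Used to assert the
#' shrinkage-freeness of low-pass smoothing.
#'
#' @param surf a [surface()].
#' @param points coordinates of the parent indexing.
#' @return Enclosed volume; positive for outward orientation.
#' @export
enclosed_volume <- function(surf, points) {
  faces <- surf$faces
  if (nrow(faces) == 0) mt_geometry_error("empty surface encloses no volume")
  ek <- c(edge_keys(faces[, c(1, 2)], nrow(points)),
          edge_keys(faces[, c(2, 3)], nrow(points)),
          edge_keys(faces[, c(3, 1)], nrow(points)))
  if (any(table(ek) != 2L))
    mt_geometry_error("surface is not closed (an edge is not shared by exactly 2 faces)")
  p0 <- points[faces[, 1], , drop = FALSE]
  p1 <- points[faces[, 2], , drop = FALSE]
  p2 <- points[faces[, 3], , drop = FALSE]
  sum(rowSums(p0 * cross3(p1, p2))) / 6
}

# Centroids of all elements (tri or tet) of a mesh.
elem_centroids <- function(m) {
  acc <- m$points[m$conn[, 1], , drop = FALSE] +
         m$points[m$conn[, 2], , drop = FALSE] +
         m$points[m$conn[, 3], , drop = FALSE]
  tet <- m$etype == 4L
  if (any(tet))
    acc[tet, ] <- acc[tet, , drop = FALSE] +
      m$points[m$conn[tet, 4], , drop = FALSE]
  acc / m$etype
}
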