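# Domain types: mesh, mesh_surface, data_field, index_mapping.

#' Construct a labeled tetrahedral/triangle mesh
#'
#' A `mesh` holds 3D vertex coordinates, a mixed tetrahedron/triangle
#' connectivity, one integer region tag per element and, optionally, one unit
#' fiber direction per element.  Region tags are the label fields of
#' image-based anatomical models (e.g. tissue vs. blood pool); every
#' higher-level operation in the package (surface extraction, submesh
#' extraction, restricted re-sampling) is driven by them.
#'
#' Vertex indices are 1-based throughout the package; the on-disk formats
#' (which are 0-based) are converted by the readers/writers.  Tetrahedra are
#' stored with positive signed volume: any negative-volume tetrahedron is
#' reoriented on construction (swapping its last two vertices) and a message
#' reports the count, so that an inverted element is always detectable as a
#' simple sign test.
#'
#' @param points numeric n x 3 matrix of vertex coordinates (units of the
#'   source data, treated as opaque).
#' @param conn integer element connectivity: an m x 4 matrix whose rows are
#'   tetrahedra, or an m x 3 matrix of triangles, or an m x 4 matrix with
#'   `NA` in column 4 marking triangle rows (mixed meshes).
#' @param tags integer region label per element; defaults to 1.
#' @param fibers optional m x 3 matrix of per-element fiber directions,
#'   carried as opaque payload through all operations.
#' @param reorient logical; reorient negative-volume tetrahedra (default TRUE).
#' @return An object of class `mesh` with fields `points`, `conn` (m x 4,
#'   `NA` fourth vertex for triangles), `etype` (3 or 4 per element), `tags`,
#'   `fibers`.
#' @examples
#' m <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'           conn = rbind(1:4))
#' m
#' @export
mesh <- function(points, conn, tags = NULL, fibers = NULL, reorient = TRUE) {
  points <- as_point_matrix(points)
  conn <- as.matrix(conn)
  if (ncol(conn) == 3) conn <- cbind(conn, NA_integer_)
  if (ncol(conn) != 4)
    mt_usage_error("conn must have 3 or 4 columns (got %d)", ncol(conn))
  storage.mode(conn) <- "integer"
  dimnames(conn) <- NULL
  etype <- ifelse(is.na(conn[, 4]), 3L, 4L)
  tags <- as.integer(tags %||% rep(1L, nrow(conn)))
  if (length(tags) == 1L) tags <- rep(tags, nrow(conn))
  if (!is.null(fibers)) fibers <- as_point_matrix(fibers, "fibers")
  m <- structure(list(points = points, conn = conn, etype = etype,
                      tags = tags, fibers = fibers),
                 class = "mesh")
  validate_mesh(m)
  if (reorient) {
    tet <- which(m$etype == 4L)
    if (length(tet)) {
      v <- tet_volumes(m$points, m$conn[tet, , drop = FALSE])
      neg <- tet[v < 0]
      if (length(neg)) {
        m$conn[neg, c(3L, 4L)] <- m$conn[neg, c(4L, 3L)]
        message(sprintf("mesh: reoriented %d inverted tetrahedra", length(neg)))
      }
    }
  }
  m
}

#' Validate mesh invariants
#'
#' Checks index ranges, per-element vertex distinctness and field length
#' consistency; signals a geometry/usage error on violation.
#'
#' @param m a [mesh].
#' @return `m`, invisibly.
#' @export
validate_mesh <- function(m) {
  stopifnot(inherits(m, "mesh"))
  n <- nrow(m$points)
  ne <- nrow(m$conn)
  if (length(m$etype) != ne || length(m$tags) != ne)
    mt_usage_error("tags/etype length (%d/%d) != element count (%d)",
                   length(m$tags), length(m$etype), ne)
  if (!is.null(m$fibers) && nrow(m$fibers) != ne)
    mt_usage_error("fibers rows (%d) != element count (%d)", nrow(m$fibers), ne)
  idx <- m$conn[cbind(rep(seq_len(ne), times = m$etype),
                      sequence(m$etype))]
  if (ne > 0 && (anyNA(idx) || min(idx) < 1L || max(idx) > n))
    mt_geometry_error("connectivity index out of range [1, %d]", n)
  tri <- m$etype == 3L
  if (any(tri)) {
    cc <- m$conn[tri, 1:3, drop = FALSE]
    if (any(cc[, 1] == cc[, 2] | cc[, 1] == cc[, 3] | cc[, 2] == cc[, 3]))
      mt_geometry_error("triangle with repeated vertex index")
  }
  if (any(!tri)) {
    cc <- m$conn[!tri, , drop = FALSE]
    dup <- cc[, 1] == cc[, 2] | cc[, 1] == cc[, 3] | cc[, 1] == cc[, 4] |
           cc[, 2] == cc[, 3] | cc[, 2] == cc[, 4] | cc[, 3] == cc[, 4]
    if (any(dup)) mt_geometry_error("tetrahedron with repeated vertex index")
  }
  invisible(m)
}

#' @export
print.mesh <- function(x, ...) {
  tb <- table(x$tags)
  cat(sprintf("mesh: %d points, %d elements (%d tets, %d triangles)\n",
              nrow(x$points), nrow(x$conn), sum(x$etype == 4L),
              sum(x$etype == 3L)))
  cat("  tags:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  if (!is.null(x$fibers)) cat("  per-element fibers present\n")
  invisible(x)
}

n_points <- function(m) nrow(m$points)
n_elems  <- function(m) nrow(m$conn)

#' Construct an oriented triangle surface
#'
#' A surface is a set of oriented triangular faces referencing the vertex
#' indexing of a parent mesh (it carries no coordinates of its own).  The
#' vertex set is recomputed from the faces.
#'
#' @param faces integer k x 3 matrix of vertex index triples; vertex order
#'   encodes orientation.
#' @param parent_point_count number of points in the parent indexing; all
#'   face indices must be below or equal to it.
#' @return An object of class `mesh_surface` with fields `faces`,
#'   `parent_point_count`, `vertex_set` (sorted unique indices).
#' @export
surface <- function(faces, parent_point_count) {
  faces <- as.matrix(faces)
  if (length(faces) == 0) faces <- matrix(integer(0), 0, 3)
  if (ncol(faces) != 3) mt_usage_error("faces must have 3 columns")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  parent_point_count <- as.integer(parent_point_count)
  if (nrow(faces) && max(faces) > parent_point_count)
    mt_geometry_error("face index exceeds parent point count %d",
                      parent_point_count)
  if (nrow(faces) && min(faces) < 1L)
    mt_geometry_error("face index below 1")
  structure(list(faces = faces,
                 parent_point_count = parent_point_count,
                 vertex_set = sort(unique(as.vector(faces)))),
            class = "mesh_surface")
}

#' @export
print.mesh_surface <- function(x, ...) {
  cat(sprintf("surface: %d faces over %d vertices (parent indexing: %d points)\n",
              nrow(x$faces), length(x$vertex_set), x$parent_point_count))
  invisible(x)
}

#' Construct a node- or element-attached data field
#'
#' Scalar (width 1) or 3-vector (width 3) values attached to the nodes or
#' elements of a mesh.  The length is validated against a mesh only when the
#' field is used, via [validate_field()].
#'
#' @param values numeric vector (scalar field) or n x 3 matrix (vector field).
#' @param attachment `"node"` or `"element"`.
#' @return An object of class `data_field` with fields `values` (always a
#'   matrix with `width` columns), `attachment`, `width`.
#' @export
data_field <- function(values, attachment = c("node", "element")) {
  attachment <- match.arg(attachment)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (!ncol(values) %in% c(1L, 3L))
    mt_usage_error("data_field width must be 1 or 3 (got %d)", ncol(values))
  structure(list(values = values, attachment = attachment,
                 width = ncol(values)),
            class = "data_field")
}

#' Validate a data field against a mesh
#'
#' @param field a [data_field].
#' @param m the [mesh] it should attach to.
#' @return `field`, invisibly; errors when the length does not match the
#'   mesh's node or element count.
#' @export
validate_field <- function(field, m) {
  need <- if (field$attachment == "node") n_points(m) else n_elems(m)
  if (nrow(field$values) != need)
    mt_usage_error("%s field length %d != mesh %s count %d",
                   field$attachment, nrow(field$values), field$attachment, need)
  invisible(field)
}

#' @export
print.data_field <- function(x, ...) {
  cat(sprintf("data_field: %d %s values, width %d\n",
              nrow(x$values), x$attachment, x$width))
  invisible(x)
}

#' Construct an index mapping from a submesh to its parent
#'
#' Injective node and element maps recording, for every node/element of an
#' extracted submesh, its index in the parent mesh.  The mapping makes
#' extraction lossless: coordinates, tags and data manipulated on the submesh
#' can be scattered back.
#'
#' @param node_map integer vector: submesh node i sits at parent node
#'   `node_map[i]`.
#' @param elem_map integer vector: submesh element j is parent element
#'   `elem_map[j]`.
#' @return An object of class `index_mapping`.
#' @export
index_mapping <- function(node_map, elem_map) {
  node_map <- as.integer(node_map); elem_map <- as.integer(elem_map)
  if (anyDuplicated(node_map) || anyDuplicated(elem_map))
    mt_usage_error("index_mapping maps must be injective")
  structure(list(node_map = node_map, elem_map = elem_map),
            class = "index_mapping")
}

#' @export
print.index_mapping <- function(x, ...) {
  cat(sprintf("index_mapping: %d nodes, %d elements\n",
              length(x$node_map), length(x$elem_map)))
  invisible(x)
}
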