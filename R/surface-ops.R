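# Surface extraction by label-set algebra and seeded edge traversal.
#
# Landmark surfaces of anatomical models (epicardium, endocardium, base) are
# definable as set operations on the boundary surfaces of label regions,
# optionally restricted to the area reachable from seed locations without
# crossing sharp edges.

#' Extract the boundary surface of a tag region set
#'
#' Returns the faces occurring exactly once among the tetrahedra whose tag is
#' in `tag_set` — the boundary of that submesh — oriented outward from the
#' submesh interior.  Canonical face identity is the sorted vertex triple.
#' If the tag set selects only triangle elements, those triangles themselves
#' are returned as the surface.
#'
#' @param m a [mesh].
#' @param tag_set non-empty set of integer region tags.
#' @return A [surface()] in the mesh's vertex indexing.
#' @export
extract_boundary_surface <- function(m, tag_set) {
  if (length(tag_set) == 0) mt_usage_error("tag_set must be non-empty")
  sel <- which(m$tags %in% tag_set)
  if (length(sel) == 0)
    mt_error("mt_empty_selection_error",
             "no element carries a tag in {%s}", paste(tag_set, collapse = ", "))
  tets <- sel[m$etype[sel] == 4L]
  if (length(tets) == 0) {
    tris <- sel[m$etype[sel] == 3L]
    faces <- m$conn[tris, 1:3, drop = FALSE]
    ord <- order(face_keys(faces, n_points(m)))
    return(surface(faces[ord, , drop = FALSE], n_points(m)))
  }
  ft <- tet_face_table(m$conn, tets)
  fk <- face_keys(ft$faces, n_points(m))
  tb <- table(fk)
  keep <- fk %in% as.numeric(names(tb)[tb == 1L])
  faces <- ft$faces[keep, , drop = FALSE]
  ord <- order(fk[keep])
  surface(faces[ord, , drop = FALSE], n_points(m))
}

check_same_parent <- function(a, b) {
  if (a$parent_point_count != b$parent_point_count)
    mt_usage_error("surfaces reference different parent indexings (%d vs %d points)",
                   a$parent_point_count, b$parent_point_count)
}

surface_setop <- function(a, b, op) {
  check_same_parent(a, b)
  n <- a$parent_point_count
  ka <- face_keys(a$faces, n); kb <- face_keys(b$faces, n)
  faces <- switch(op,
    union = {
      extra <- !(kb %in% ka)
      rbind(a$faces, b$faces[extra, , drop = FALSE])
    },
    intersection = a$faces[ka %in% kb, , drop = FALSE],
    difference = a$faces[!(ka %in% kb), , drop = FALSE])
  if (nrow(faces)) faces <- faces[order(face_keys(faces, n)), , drop = FALSE]
  surface(faces, n)
}

#' Set algebra on surfaces
#'
#' Set union, intersection and difference over canonical face keys (sorted
#' vertex triples).  Orientation is taken from `a` where a face is present in
#' `a`, else from `b`; output faces are sorted by key, hence deterministic.
#'
#' @param a,b [surface()]s over the same parent vertex indexing.
#' @return A [surface()].
#' @export
surface_union <- function(a, b) surface_setop(a, b, "union")

#' @rdname surface_union
#' @export
surface_intersection <- function(a, b) surface_setop(a, b, "intersection")

#' @rdname surface_union
#' @export
surface_difference <- function(a, b) surface_setop(a, b, "difference")

#' Restrict a surface to the area reachable from seed locations
#'
#' From each seed coordinate, snaps to the nearest surface vertex and runs a
#' shortest-path traversal over surface edges with Euclidean edge weights.
#' An edge is impassable when the normals of its two adjacent faces deviate
#' by more than `block_angle_deg` (a critical edge curvature).  A face is
#' kept when all three of its vertices were reached within
#' `max_edge_distance` from the same seed; the result is the union over
#' seeds.
#'
#' @param surf a [surface()].
#' @param points parent coordinates.
#' @param seeds numeric s x 3 matrix (or length-3 vector) of seed locations.
#' @param max_edge_distance geodesic-along-edges distance limit
#'   (default `Inf`).
#' @param block_angle_deg critical edge curvature in degrees; `NULL`
#'   disables blocking.
#' @param snap_radius seeds farther than this from the surface are snapped
#'   with a warning (never silently); default 5% of the bounding-box
#'   diagonal.
#' @return The restricted [surface()] (a subset of `surf`).
#' @export
restrict_by_traversal <- function(surf, points, seeds,
                                  max_edge_distance = Inf,
                                  block_angle_deg = NULL,
                                  snap_radius = NULL) {
  if (nrow(surf$faces) == 0) mt_usage_error("surface is empty")
  seeds <- if (is.null(dim(seeds))) rbind(seeds) else as.matrix(seeds)
  if (nrow(seeds) == 0) mt_usage_error("at least one seed is required")
  snap_radius <- snap_radius %||% (0.05 * bbox_diagonal(points))

  faces <- surf$faces
  n <- nrow(points)
  fe <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  fe_face <- rep(seq_len(nrow(faces)), 3L)
  ek <- edge_keys(fe, n)
  uek <- sort(unique(ek))
  pos <- match(ek, uek)
  first <- match(uek, ek)
  ue <- cbind(pmin(fe[first, 1], fe[first, 2]),
              pmax(fe[first, 1], fe[first, 2]), deparse.level = 0)

  efaces_all <- split(fe_face, pos)
  names(efaces_all) <- NULL
  passable <- rep(TRUE, nrow(ue))
  if (!is.null(block_angle_deg)) {
    fnorm <- triangle_normals(points, faces)
    two <- which(lengths(efaces_all) == 2L)
    if (length(two)) {
      f1 <- vapply(efaces_all[two], `[`, integer(1), 1L)
      f2 <- vapply(efaces_all[two], `[`, integer(1), 2L)
      ang <- normal_angle_deg(fnorm[f1, , drop = FALSE],
                              fnorm[f2, , drop = FALSE])
      passable[two] <- ang <= block_angle_deg
    }
    passable[lengths(efaces_all) > 2L] <- FALSE  # non-manifold: block
  }
  keep_e <- ue[passable, , drop = FALSE]

  verts <- surf$vertex_set
  vmap <- integer(n); vmap[verts] <- seq_along(verts)

  seed_v <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    np <- nearest_point(points[verts, , drop = FALSE], seeds[i, ])
    if (np$dist > snap_radius)
      warning(sprintf("seed %d is %.3g from the surface (snap radius %.3g); snapped to nearest vertex",
                      i, np$dist, snap_radius))
    seed_v[i] <- np$index
  }

  # vertex distances along passable edges
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  if (nrow(keep_e)) {
    g <- igraph::add_edges(g, as.vector(rbind(vmap[keep_e[, 1]],
                                              vmap[keep_e[, 2]])))
    igraph::E(g)$weight <- edge_lengths(points, keep_e)
  }
  d <- igraph::distances(g, v = seed_v, weights = igraph::E(g)$weight)

  # face region growing: two faces communicate across a passable edge only
  # (blocked edges cut the face adjacency, so traversal cannot leak around a
  # sharp crease through its vertices)
  dual <- igraph::make_empty_graph(n = nrow(faces), directed = FALSE)
  two_pass <- which(passable & lengths(efaces_all) == 2L)
  if (length(two_pass)) {
    f1 <- vapply(efaces_all[two_pass], `[`, integer(1), 1L)
    f2 <- vapply(efaces_all[two_pass], `[`, integer(1), 2L)
    dual <- igraph::add_edges(dual, as.vector(rbind(f1, f2)))
  }
  comp <- igraph::components(dual)$membership
  fv <- cbind(vmap[faces[, 1]], vmap[faces[, 2]], vmap[faces[, 3]])

  keep_face <- rep(FALSE, nrow(faces))
  for (s in seq_len(nrow(seeds))) {
    seed_faces <- which(fv[, 1] == seed_v[s] | fv[, 2] == seed_v[s] |
                        fv[, 3] == seed_v[s])
    in_region <- comp %in% unique(comp[seed_faces])
    reached <- d[s, ] <= max_edge_distance
    keep_face <- keep_face |
      (in_region & reached[fv[, 1]] & reached[fv[, 2]] & reached[fv[, 3]])
  }
  faces <- faces[keep_face, , drop = FALSE]
  if (nrow(faces)) faces <- faces[order(face_keys(faces, n)), , drop = FALSE]
  surface(faces, n)
}

#' Euler characteristic of a surface
#'
#' `V - E + F`; equals 2 for a closed surface of a topological ball.
#'
#' @param surf a [surface()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(surf) {
  f <- surf$faces
  n <- surf$parent_point_count
  ek <- unique(c(edge_keys(f[, c(1, 2)], n), edge_keys(f[, c(2, 3)], n),
                 edge_keys(f[, c(3, 1)], n)))
  length(surf$vertex_set) - length(ek) + nrow(f)
}
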