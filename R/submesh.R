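# Submesh extraction/insertion with invertible mappings, data transfer,
# proximity-based overlap extraction, and mesh merging.

# Extract the given element indices into a compact submesh + mapping.
extract_elements <- function(m, elems) {
  elems <- sort(unique(as.integer(elems)))
  verts <- sort(unique(as.vector(
    m$conn[cbind(rep(elems, times = m$etype[elems]), sequence(m$etype[elems]))])))
  vmap <- integer(n_points(m)); vmap[verts] <- seq_along(verts)
  conn <- m$conn[elems, , drop = FALSE]
  tri <- m$etype[elems] == 3L
  if (any(!tri)) conn[!tri, ] <- matrix(vmap[conn[!tri, ]], ncol = 4)
  if (any(tri)) conn[tri, 1:3] <- matrix(vmap[conn[tri, 1:3]], ncol = 3)
  sub <- mesh(m$points[verts, , drop = FALSE], conn, tags = m$tags[elems],
              fibers = if (!is.null(m$fibers)) m$fibers[elems, , drop = FALSE],
              reorient = FALSE)
  list(mesh = sub, mapping = index_mapping(verts, elems))
}

#' Extract the submesh of a tag region set
#'
#' Returns the elements whose tag is in `tag_set`, with vertices renumbered
#' compactly (preserving relative order), together with an [index_mapping()]
#' that makes re-insertion lossless.  Tags and fibers are carried over.
#'
#' @param m a [mesh].
#' @param tag_set integer region tags.
#' @return `list(mesh = <mesh>, mapping = <index_mapping>)`.
#' @export
extract_submesh <- function(m, tag_set) {
  elems <- which(m$tags %in% tag_set)
  if (length(elems) == 0)
    mt_error("mt_empty_selection_error",
             "no element carries a tag in {%s}", paste(tag_set, collapse = ", "))
  extract_elements(m, elems)
}

#' Re-insert a manipulated submesh into its parent
#'
#' Overwrites the mapped node coordinates, element tags and fibers of the
#' parent with those of the submesh.  Only topology-preserving edits are
#' insertable: if the submesh's node or element count no longer matches the
#' mapping (e.g. after re-sampling), a mapping-stale error is signalled and
#' the submesh must be re-extracted.
#'
#' @param parent the parent [mesh].
#' @param sub the manipulated submesh.
#' @param mapping the [index_mapping()] from extraction.
#' @return The updated parent [mesh].
#' @export
insert_submesh <- function(parent, sub, mapping) {
  if (n_points(sub) != length(mapping$node_map) ||
      n_elems(sub) != length(mapping$elem_map))
    mt_error("mt_mapping_stale_error",
             "submesh size (%d nodes / %d elems) does not match mapping (%d / %d); re-extract after topology changes",
             n_points(sub), n_elems(sub),
             length(mapping$node_map), length(mapping$elem_map))
  parent$points[mapping$node_map, ] <- sub$points
  parent$tags[mapping$elem_map] <- sub$tags
  if (!is.null(sub$fibers)) {
    if (is.null(parent$fibers))
      parent$fibers <- matrix(0, n_elems(parent), 3)
    parent$fibers[mapping$elem_map, ] <- sub$fibers
  }
  parent
}

#' Gather a data field onto a submesh
#'
#' @param field a [data_field()] on the parent.
#' @param mapping the [index_mapping()] of the submesh.
#' @return The gathered [data_field()] on the submesh.
#' @export
extract_data <- function(field, mapping) {
  idx <- if (field$attachment == "node") mapping$node_map else mapping$elem_map
  if (max(idx) > nrow(field$values))
    mt_usage_error("mapping index %d exceeds field length %d",
                   max(idx), nrow(field$values))
  data_field(field$values[idx, , drop = FALSE], field$attachment)
}

#' Scatter a submesh data field back into the parent field
#'
#' @param parent_field the parent [data_field()] (unmapped entries are
#'   untouched).
#' @param sub_field the submesh field.
#' @param mapping the [index_mapping()] of the submesh.
#' @return The updated parent [data_field()].
#' @export
insert_data <- function(parent_field, sub_field, mapping) {
  if (parent_field$attachment != sub_field$attachment ||
      parent_field$width != sub_field$width)
    mt_usage_error("parent and submesh fields disagree in attachment/width")
  idx <- if (sub_field$attachment == "node") mapping$node_map else mapping$elem_map
  if (nrow(sub_field$values) != length(idx))
    mt_usage_error("submesh field length %d != mapping length %d",
                   nrow(sub_field$values), length(idx))
  parent_field$values[idx, ] <- sub_field$values
  parent_field
}

#' Extract the elements of one mesh overlapping another
#'
#' The overlap is the set of `msh1` elements whose centroid lies within
#' distance `size` of any vertex of `msh2` (a uniform-grid spatial index
#' keeps this near-linear); the complement is every other element.  Both are
#' returned with mappings, and they partition `msh1` exactly.  An empty
#' overlap (distant `msh2`) is legal.
#'
#' @param msh1 the [mesh] to partition.
#' @param msh2 the probing mesh (or any object with a `points` matrix).
#' @param size capture distance in mesh coordinate units (>= 0).
#' @return `list(overlap = list(mesh, mapping), complement = list(mesh,
#'   mapping))`; an empty side has a `NULL` mesh and empty mapping.
#' @export
extract_overlap <- function(msh1, msh2, size) {
  if (size < 0) mt_usage_error("size must be >= 0")
  cen <- elem_centroids(msh1)
  pts2 <- if (inherits(msh2, "mesh")) msh2$points else as_point_matrix(msh2)
  hit <- within_radius_any(cen, pts2, size)
  rest <- setdiff(seq_len(n_elems(msh1)), hit)
  side <- function(idx) {
    if (length(idx) == 0)
      list(mesh = NULL, mapping = index_mapping(integer(0), integer(0)))
    else extract_elements(msh1, idx)
  }
  list(overlap = side(hit), complement = side(rest))
}

#' Merge two meshes, unifying nearby vertices
#'
#' Concatenates the point lists, then maps every `msh2` vertex lying within
#' `tolerance` of a `msh1` vertex onto its nearest `msh1` vertex (ties broken
#' by the lowest `msh1` index) and rewrites the `msh2` connectivity.
#' Elements, tags and fibers are concatenated; `msh1` entities keep their
#' indices.  Tolerance 0 unifies only bit-identical coordinates.
#'
#' @param msh1,msh2 [mesh]es.
#' @param tolerance unification distance; default `1e-6 *` the combined
#'   bounding-box diagonal.
#' @return The merged [mesh].
#' @export
merge_meshes <- function(msh1, msh2, tolerance = NULL) {
  tolerance <- tolerance %||%
    (1e-6 * bbox_diagonal(rbind(msh1$points, msh2$points)))
  if (tolerance < 0) mt_usage_error("tolerance must be >= 0")
  n1 <- n_points(msh1); n2 <- n_points(msh2)
  map2 <- integer(n2)
  if (n1 > 0 && n2 > 0) {
    if (tolerance == 0) {
      k1 <- paste(msh1$points[, 1], msh1$points[, 2], msh1$points[, 3])
      k2 <- paste(msh2$points[, 1], msh2$points[, 2], msh2$points[, 3])
      map2 <- match(k2, k1)
      map2[is.na(map2)] <- 0L
    } else {
      gi <- grid_index(msh1$points, tolerance)
      for (i in seq_len(n2)) {
        cand <- grid_candidates(gi, msh2$points[i, ])
        if (length(cand) == 0) next
        d2 <- (msh1$points[cand, 1] - msh2$points[i, 1])^2 +
              (msh1$points[cand, 2] - msh2$points[i, 2])^2 +
              (msh1$points[cand, 3] - msh2$points[i, 3])^2
        ok <- d2 <= tolerance^2
        if (any(ok)) {
          cand <- cand[ok]; d2 <- d2[ok]
          best <- cand[d2 == min(d2)]
          map2[i] <- min(best)
        }
      }
    }
  }
  new_ids <- integer(n2)
  fresh <- map2 == 0L
  new_ids[fresh] <- n1 + seq_len(sum(fresh))
  new_ids[!fresh] <- map2[!fresh]
  pts <- rbind(msh1$points, msh2$points[fresh, , drop = FALSE])
  conn2 <- msh2$conn
  tri <- msh2$etype == 3L
  if (any(!tri)) conn2[!tri, ] <- matrix(new_ids[conn2[!tri, ]], ncol = 4)
  if (any(tri)) conn2[tri, 1:3] <- matrix(new_ids[conn2[tri, 1:3]], ncol = 3)
  # unification collapsing an element onto itself is a modelling error
  for (j in seq_len(nrow(conn2))) {
    vs <- conn2[j, seq_len(msh2$etype[j])]
    if (anyDuplicated(vs))
      mt_geometry_error("vertex unification degenerates msh2 element %d; lower the tolerance", j)
  }
  fib <- NULL
  if (!is.null(msh1$fibers) || !is.null(msh2$fibers)) {
    f1 <- msh1$fibers %||% matrix(0, n_elems(msh1), 3)
    f2 <- msh2$fibers %||% matrix(0, n_elems(msh2), 3)
    fib <- rbind(f1, f2)
  }
  mesh(pts, rbind(msh1$conn, conn2), tags = c(msh1$tags, msh2$tags),
       fibers = fib, reorient = FALSE)
}
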