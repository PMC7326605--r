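# Mesh-derived adjacency structures.

# All element edges as an (n_edge_instances x 2) matrix plus the owning
# element index per row.  Tets contribute 6 edges, triangles 3.
elem_edge_instances <- function(conn, etype) {
  tet <- which(etype == 4L); tri <- which(etype == 3L)
  pairs4 <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  pairs3 <- rbind(c(1, 2), c(1, 3), c(2, 3))
  eds <- list(); own <- list(); k <- 0L
  if (length(tet)) for (r in seq_len(6)) {
    k <- k + 1L
    eds[[k]] <- cbind(conn[tet, pairs4[r, 1]], conn[tet, pairs4[r, 2]])
    own[[k]] <- tet
  }
  if (length(tri)) for (r in seq_len(3)) {
    k <- k + 1L
    eds[[k]] <- cbind(conn[tri, pairs3[r, 1]], conn[tri, pairs3[r, 2]])
    own[[k]] <- tri
  }
  list(edges = do.call(rbind, eds), elem = unlist(own))
}

# Oriented outward faces of the given tetrahedra (positive-volume vertex
# order assumed): one row per (tet, face), normals pointing away from the
# opposite vertex.
tet_face_table <- function(conn, elems) {
  cc <- conn[elems, , drop = FALSE]
  faces <- rbind(cc[, c(1, 3, 2)], cc[, c(1, 2, 4)],
                 cc[, c(2, 3, 4)], cc[, c(1, 4, 3)])
  list(faces = faces, elem = rep(elems, 4L))
}

#' Build adjacency structures from mesh connectivity
#'
#' Derives the traversal graphs most algorithms need: per-node incident
#' elements, the unique edge list, per-edge incident elements, and
#' face-sharing (tet) / edge-sharing (triangle) element adjacency.  All
#' orderings are sorted, hence deterministic.
#'
#' @param m a [mesh].
#' @return An object of class `mesh_graph` with fields `node_to_elems`
#'   (list), `unique_edges` (k x 2 matrix, lo < hi, sorted), `edge_to_elems`
#'   (list parallel to `unique_edges`), `elem_to_elems` (list).
#' @export
mesh_graph <- function(m) {
  n <- n_points(m); ne <- n_elems(m)
  ei <- elem_edge_instances(m$conn, m$etype)
  lo <- pmin(ei$edges[, 1], ei$edges[, 2])
  hi <- pmax(ei$edges[, 1], ei$edges[, 2])
  key <- tuple_key(cbind(lo, hi), n + 1)
  ukey <- sort(unique(key))
  pos <- match(key, ukey)
  first <- match(ukey, key)
  unique_edges <- cbind(lo[first], hi[first], deparse.level = 0)
  edge_to_elems <- lapply(split(ei$elem, pos), function(x) sort(unique(x)))
  names(edge_to_elems) <- NULL

  vlist <- m$conn[cbind(rep(seq_len(ne), times = m$etype), sequence(m$etype))]
  node_to_elems <- rep(list(integer(0)), n)
  got <- split(rep(seq_len(ne), times = m$etype), vlist)
  node_to_elems[as.integer(names(got))] <- lapply(got, function(x) sort(unique(x)))

  elem_to_elems <- rep(list(integer(0)), ne)
  tet <- which(m$etype == 4L)
  if (length(tet)) {
    ft <- tet_face_table(m$conn, tet)
    fk <- face_keys(ft$faces, n)
    o <- order(fk)
    fk <- fk[o]; fe <- ft$elem[o]
    shared <- which(fk[-1] == fk[-length(fk)])
    if (length(shared)) {
      a <- fe[shared]; b <- fe[shared + 1L]
      adj <- split(c(b, a), c(a, b))
      elem_to_elems[as.integer(names(adj))] <- lapply(adj, function(x) sort(unique(x)))
    }
  }
  tri <- which(m$etype == 3L)
  if (length(tri)) {
    tri_rows <- ei$elem %in% tri
    te <- key[tri_rows]; to <- ei$elem[tri_rows]
    grp <- split(to, te)
    grp <- grp[lengths(grp) > 1]
    if (length(grp)) {
      a <- unlist(lapply(grp, function(g) rep(g, each = length(g))))
      b <- unlist(lapply(grp, function(g) rep(g, times = length(g))))
      keep <- a != b
      adj <- split(b[keep], a[keep])
      ids <- as.integer(names(adj))
      elem_to_elems[ids] <- Map(function(old, new) sort(unique(c(old, new))),
                                elem_to_elems[ids], adj)
    }
  }
  structure(list(node_to_elems = node_to_elems,
                 unique_edges = unique_edges,
                 edge_to_elems = edge_to_elems,
                 elem_to_elems = elem_to_elems),
            class = "mesh_graph")
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("mesh_graph: %d nodes, %d unique edges\n",
              length(x$node_to_elems), nrow(x$unique_edges)))
  invisible(x)
}

edge_lengths <- function(points, edges) {
  row_norms(points[edges[, 1], , drop = FALSE] -
            points[edges[, 2], , drop = FALSE])
}
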