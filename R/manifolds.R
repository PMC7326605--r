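# Volumetric / surface / line manifold decomposition.
#
# Smoothing a labeled volumetric mesh must keep region interfaces and sharp
# feature lines intact: a vertex may only be averaged with neighbours of its
# own manifold.  This file classifies vertices into VOLUME (interior of one
# region), SURFACE (outer boundary or two-region interface), LINE (patch
# junctions and sharp feature edges) and POINT (line junctions, never moved),
# and builds the restricted neighbour sets the smoother averages over.

OUTSIDE_PATCH <- "ext"  # reserved pseudo-tag for the outer boundary

# Boundary + interface faces of a tet mesh, oriented outward from the
# lower-tag side; patch id = "a|b" over sorted tag pair, outer boundary
# "tag|ext".  Errors on non-manifold face multiplicity.
patch_face_set <- function(m, tets = which(m$etype == 4L)) {
  ft <- tet_face_table(m$conn, tets)
  fk <- face_keys(ft$faces, n_points(m))
  o <- order(fk)
  fk <- fk[o]
  runs <- rle(fk)
  if (any(runs$lengths > 2))
    mt_geometry_error("non-manifold tet mesh: a face is shared by >2 tetrahedra")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  single <- runs$lengths == 1L
  out_faces <- list(); out_patch <- list(); k <- 0L
  if (any(single)) {
    i <- o[starts[single]]
    k <- k + 1L
    out_faces[[k]] <- ft$faces[i, , drop = FALSE]
    out_patch[[k]] <- paste0(m$tags[ft$elem[i]], "|", OUTSIDE_PATCH)
  }
  if (any(!single)) {
    i1 <- o[starts[!single]]; i2 <- o[ends[!single]]
    t1 <- m$tags[ft$elem[i1]]; t2 <- m$tags[ft$elem[i2]]
    iface <- t1 != t2
    if (any(iface)) {
      lo_first <- t1[iface] < t2[iface]
      pick <- ifelse(lo_first, i1[iface], i2[iface])
      k <- k + 1L
      out_faces[[k]] <- ft$faces[pick, , drop = FALSE]
      out_patch[[k]] <- paste0(pmin(t1[iface], t2[iface]), "|",
                               pmax(t1[iface], t2[iface]))
    }
  }
  faces <- do.call(rbind, out_faces) %||% matrix(integer(0), 0, 3)
  patch <- unlist(out_patch) %||% character(0)
  ord <- order(face_keys(faces, n_points(m)))
  list(faces = faces[ord, , drop = FALSE], patch = patch[ord])
}

# Angle in degrees between consistently oriented unit normals.
normal_angle_deg <- function(n1, n2) {
  d <- pmin(1, pmax(-1, rowSums(n1 * n2)))
  acos(d) * 180 / pi
}

#' Decompose a mesh into volume, surface, line and point manifolds
#'
#' Classifies every vertex of a tagged tetrahedral mesh (or a standalone
#' triangle mesh) and builds the per-vertex neighbour sets over which
#' low-pass smoothing averages are taken:
#'
#' * `VOLUME` — interior of a single tag region; averages over all
#'   edge-connected neighbours.
#' * `SURFACE` — on the outer boundary or on the interface between two tag
#'   regions; averages only over neighbours on the same interface patch
#'   (patches are identified by unordered tag pairs, the outer boundary by a
#'   reserved pseudo-tag).
#' * `LINE` — where three or more patches meet, or on a surface edge whose
#'   adjacent face normals deviate by more than `feature_angle_deg`;
#'   averages only along the line.
#' * `POINT` — where three or more line branches meet (or a line ends);
#'   never moved.
#'
#' Triangle-only meshes are treated as a single surface manifold with
#' LINE/POINT detection on boundary and sharp edges.
#'
#' @param m a [mesh].
#' @param graph optional precomputed [mesh_graph()].
#' @param feature_angle_deg dihedral deviation (degrees) above which a
#'   surface edge becomes a feature line.  Default 40.
#' @return An object of class `manifold_labeling`: `vertex_class` (character
#'   per vertex), `patch_id` (character, `NA` off-surface), `neighbor_sets`
#'   (list of integer vectors), plus the patch face set and line edges used.
#' @export
decompose_manifolds <- function(m, graph = NULL, feature_angle_deg = 40) {
  n <- n_points(m)
  graph <- graph %||% mesh_graph(m)
  has_tet <- any(m$etype == 4L)
  if (has_tet) {
    pf <- patch_face_set(m)
  } else {
    pf <- list(faces = m$conn[m$etype == 3L, 1:3, drop = FALSE],
               patch = rep("surf", sum(m$etype == 3L)))
  }
  faces <- pf$faces; patch <- pf$patch
  nf <- nrow(faces)

  vclass <- rep("VOLUME", n)
  on_surf <- sort(unique(as.vector(faces)))
  vclass[on_surf] <- "SURFACE"
  if (!has_tet) {
    # isolated vertices of a pure surface mesh are pinned
    vclass[setdiff(seq_len(n), on_surf)] <- "POINT"
  }

  # surface edges: 3 per patch face
  fe <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  fe_face <- rep(seq_len(nf), 3L)
  ek <- edge_keys(fe, n)
  uek <- sort(unique(ek))
  pos <- match(ek, uek)
  edge_faces <- split(fe_face, pos)
  names(edge_faces) <- NULL
  first <- match(uek, ek)
  ue <- cbind(pmin(fe[first, 1], fe[first, 2]),
              pmax(fe[first, 1], fe[first, 2]), deparse.level = 0)

  fnorm <- triangle_normals(m$points, faces)
  nfaces_per_edge <- lengths(edge_faces)
  line_edge <- logical(length(edge_faces))
  # non-manifold or boundary edges of the patch complex
  line_edge[nfaces_per_edge != 2L] <- TRUE
  two <- which(nfaces_per_edge == 2L)
  if (length(two)) {
    f1 <- vapply(edge_faces[two], `[`, integer(1), 1L)
    f2 <- vapply(edge_faces[two], `[`, integer(1), 2L)
    diff_patch <- patch[f1] != patch[f2]
    ang <- normal_angle_deg(fnorm[f1, , drop = FALSE], fnorm[f2, , drop = FALSE])
    line_edge[two] <- diff_patch | ang > feature_angle_deg
  }
  line_edges <- ue[line_edge, , drop = FALSE]

  lv <- sort(unique(as.vector(line_edges)))
  vclass[lv] <- "LINE"
  # vertices touching >= 3 distinct patches are junction lines too
  vp_patch <- split(rep(patch, 3L), as.vector(faces))
  vp_patch <- lapply(vp_patch, unique)
  multi <- as.integer(names(vp_patch))[lengths(vp_patch) >= 3L]
  vclass[setdiff(multi, which(vclass == "POINT"))] <- "LINE"

  if (nrow(line_edges)) {
    deg <- tabulate(as.vector(line_edges), nbins = n)
    vclass[deg >= 3L | (deg == 1L & vclass == "LINE")] <- "POINT"
  }

  patch_id <- rep(NA_character_, n)
  patch_id[as.integer(names(vp_patch))] <-
    vapply(vp_patch, function(p) sort(p)[1], character(1))

  # neighbour sets
  eadj <- graph$unique_edges
  adj <- split(c(eadj[, 2], eadj[, 1]), c(eadj[, 1], eadj[, 2]))
  neighbor_sets <- rep(list(integer(0)), n)
  vol <- which(vclass == "VOLUME")
  hit <- intersect(as.character(vol), names(adj))
  neighbor_sets[as.integer(hit)] <- lapply(adj[hit], function(x) sort(unique(x)))

  surf_v <- which(vclass == "SURFACE")
  if (length(surf_v) && nrow(ue)) {
    # neighbour u of v over a surface edge carrying v's patch
    epatch <- lapply(edge_faces, function(fs) unique(patch[fs]))
    reps <- lengths(epatch)
    ev1 <- rep(ue[, 1], reps); ev2 <- rep(ue[, 2], reps)
    ep <- unlist(epatch)
    k1 <- paste(ev1, ep); k2 <- paste(ev2, ep)
    nb <- split(c(ev2, ev1), c(k1, k2))
    want <- paste(surf_v, patch_id[surf_v])
    got <- nb[want]
    got[vapply(got, is.null, logical(1))] <- list(integer(0))
    neighbor_sets[surf_v] <- lapply(got, function(x) sort(unique(x)))
  }
  line_v <- which(vclass == "LINE")
  if (length(line_v) && nrow(line_edges)) {
    ladj <- split(c(line_edges[, 2], line_edges[, 1]),
                  c(line_edges[, 1], line_edges[, 2]))
    hit <- intersect(as.character(line_v), names(ladj))
    neighbor_sets[as.integer(hit)] <- lapply(ladj[hit], function(x) sort(unique(x)))
  }
  neighbor_sets[vclass == "POINT"] <- list(integer(0))

  structure(list(vertex_class = vclass, patch_id = patch_id,
                 neighbor_sets = neighbor_sets,
                 patch_faces = pf, line_edges = line_edges,
                 feature_angle_deg = feature_angle_deg),
            class = "manifold_labeling")
}

#' @export
print.manifold_labeling <- function(x, ...) {
  tb <- table(factor(x$vertex_class,
                     levels = c("VOLUME", "SURFACE", "LINE", "POINT")))
  cat("manifold_labeling:",
      paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}
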