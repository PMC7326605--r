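# Shrinkage-free (Taubin) low-pass smoothing of mesh coordinates and data.
#
# Plain Laplacian smoothing contracts every neighbourhood towards its local
# average and, on closed surfaces, shrinks the enclosed volume.  Taubin's
# scheme alternates a forward step (lambda > 0, towards the average) with a
# backward step (mu < -lambda, away from it); the pair acts as a low-pass
# filter that damps noise while preserving volume.  Averages are restricted
# to each vertex's manifold neighbour set so region interfaces and feature
# lines smooth within themselves instead of bleeding across.

#' Smoothing parameters
#'
#' One iteration is one lambda pass followed by one mu pass.  The default
#' pair lambda = 0.5, mu = -0.505 sets a narrow pass band
#' (`1/lambda + 1/mu` of about 0.02): wide enough to keep the smoother a
#' genuine low-pass filter, narrow enough that the lowest geometric modes of
#' a typical closed surface are neither damped nor amplified measurably over
#' hundreds of iterations — which is what keeps enclosed volume stable.
#' `mu = 0` degenerates to plain Laplacian smoothing (used as the shrinkage
#' control in tests).
#'
#' @param lambda forward step in (0, 1).
#' @param mu backward step, `mu < 0` and `|mu| > lambda` for the low-pass
#'   condition; 0 gives plain Laplacian smoothing.
#' @param iterations non-negative integer.
#' @param quality_threshold element quality in `[0, 1]` below which vertex
#'   updates are reverted, or `NULL` to disable tracking (tetrahedral meshes
#'   only).
#' @param metric quality metric used by the guard.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(lambda = 0.5, mu = -0.505, iterations = 100L,
                             quality_threshold = NULL,
                             metric = c("volume_edge_ratio",
                                        "min_dihedral_sine")) {
  metric <- match.arg(metric)
  if (lambda <= 0 || lambda >= 1) mt_usage_error("lambda must be in (0, 1)")
  if (mu > 0) mt_usage_error("mu must be <= 0")
  if (iterations < 0) mt_usage_error("iterations must be >= 0")
  if (!is.null(quality_threshold) &&
      (quality_threshold < 0 || quality_threshold > 1))
    mt_usage_error("quality_threshold must be in [0, 1]")
  structure(list(lambda = lambda, mu = mu, iterations = as.integer(iterations),
                 quality_threshold = quality_threshold, metric = metric),
            class = "smoothing_params")
}

# Row-normalised sparse averaging operator from neighbour sets.
neighbor_average_op <- function(neighbor_sets, n) {
  deg <- lengths(neighbor_sets)
  i <- rep(seq_len(n), deg)
  j <- unlist(neighbor_sets, use.names = FALSE)
  if (length(j) == 0) return(NULL)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
}

# One synchronous (Jacobi) smoothing pass with optional per-vertex quality
# revert.  Returns updated positions.
smooth_pass <- function(pts, W, movable, step, guard) {
  avg <- as.matrix(W %*% pts)
  prop <- pts
  prop[movable, ] <- pts[movable, , drop = FALSE] +
    step * (avg[movable, , drop = FALSE] - pts[movable, , drop = FALSE])
  if (is.null(guard)) return(prop)
  q_old <- elem_quality(pts, guard$conn, guard$metric)
  reverted <- rep(FALSE, nrow(pts))
  thr <- guard$threshold
  repeat {
    q_new <- elem_quality(prop, guard$conn, guard$metric)
    bad <- (q_new < thr & q_old >= thr) | (q_new < q_old & q_old < thr)
    if (!any(bad)) break
    vb <- unique(as.vector(guard$conn[bad, , drop = FALSE]))
    vb <- vb[!reverted[vb]]
    if (length(vb) == 0) break  # cannot improve further; keep reverted state
    reverted[vb] <- TRUE
    prop[vb, ] <- pts[vb, , drop = FALSE]
  }
  prop
}

#' Taubin smoothing of mesh coordinates
#'
#' Each iteration displaces every movable vertex towards the mean of its
#' manifold neighbour set by `lambda`, then away by `mu` (synchronous
#' updates, so results are independent of vertex order).  POINT-class
#' vertices never move.  With `quality_threshold` set (tetrahedral meshes
#' only), a vertex update is reverted whenever an incident tetrahedron's
#' quality would drop below the threshold while currently above it, or would
#' decrease further while already below it — the threshold is never crossed
#' downwards.
#'
#' @param m a [mesh].
#' @param labeling a [decompose_manifolds()] labeling of `m`; computed at
#'   default settings when `NULL`.
#' @param params a [smoothing_params()].
#' @return The smoothed [mesh].
#' @export
taubin_smooth <- function(m, labeling = NULL, params = smoothing_params()) {
  labeling <- labeling %||% decompose_manifolds(m)
  if (length(labeling$vertex_class) != n_points(m))
    mt_usage_error("labeling size (%d) does not match mesh point count (%d)",
                   length(labeling$vertex_class), n_points(m))
  n <- n_points(m)
  W <- neighbor_average_op(labeling$neighbor_sets, n)
  if (is.null(W) || params$iterations == 0L) return(m)
  movable <- labeling$vertex_class != "POINT" &
    lengths(labeling$neighbor_sets) > 0
  guard <- NULL
  if (!is.null(params$quality_threshold)) {
    tet <- which(m$etype == 4L)
    if (length(tet) == 0)
      mt_geometry_error("quality tracking is only supported for tetrahedral meshes")
    guard <- list(conn = m$conn[tet, , drop = FALSE],
                  metric = params$metric,
                  threshold = params$quality_threshold)
  }
  pts <- m$points
  for (it in seq_len(params$iterations)) {
    pts <- smooth_pass(pts, W, movable, params$lambda, guard)
    if (params$mu != 0)
      pts <- smooth_pass(pts, W, movable, params$mu, guard)
  }
  m$points <- pts
  m
}

#' Taubin smoothing of a node data field
#'
#' Applies the same lambda/mu two-pass updates componentwise over plain
#' edge-neighbour averages of the mesh graph.
#'
#' @param field a node-attached [data_field()] (width 1 or 3).
#' @param graph a [mesh_graph()] of the mesh the field lives on.
#' @param params a [smoothing_params()].
#' @return The smoothed [data_field()].
#' @export
smooth_data <- function(field, graph, params = smoothing_params()) {
  if (field$attachment != "node")
    mt_usage_error("only node-attached fields can be smoothed")
  n <- length(graph$node_to_elems)
  if (nrow(field$values) != n)
    mt_usage_error("field length %d != graph node count %d",
                   nrow(field$values), n)
  e <- graph$unique_edges
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  sets <- rep(list(integer(0)), n)
  sets[as.integer(names(adj))] <- adj
  W <- neighbor_average_op(sets, n)
  if (is.null(W)) return(field)
  movable <- lengths(sets) > 0
  x <- field$values
  for (it in seq_len(params$iterations)) {
    x <- smooth_pass(x, W, movable, params$lambda, NULL)
    if (params$mu != 0) x <- smooth_pass(x, W, movable, params$mu, NULL)
  }
  field$values <- x
  field
}
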