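# Deterministic generators of labeled synthetic meshes.  These emulate the
# inputs of image-based cardiac model building — multi-label volumetric
# meshes, a two-label "tissue + blood pool" geometry, a CAD-like device
# surface — so every operation in the package is testable without external
# data.

# Kuhn (path-simplex) split of the unit cube: 6 positively oriented tets
# whose induced face triangulations agree between neighbouring cubes.
kuhn_tets <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- c(1, -1, -1, 1, 1, -1)
  lapply(seq_len(6), function(i) {
    e <- diag(3)
    v0 <- c(0, 0, 0)
    v1 <- v0 + e[perms[i, 1], ]
    v2 <- v1 + e[perms[i, 2], ]
    v3 <- c(1, 1, 1)
    out <- rbind(v0, v1, v2, v3)
    if (signs[i] < 0) out <- out[c(1, 2, 4, 3), ]
    out
  })
})

#' Structured multi-label box of tetrahedra
#'
#' A structured `nx x ny x nz` grid of unit cubes (edge length `h`), each
#' split into 6 conforming, positively oriented tetrahedra.  Region tags are
#' assigned by axis-aligned label planes: an element's tag is 1 plus the
#' number of plane coordinates below its centroid along the chosen axis.
#'
#' @param nx,ny,nz number of cubes per axis.
#' @param h cube edge length.
#' @param label_planes optional list `list(axis = "z", at = c(...))` of
#'   cutting plane coordinates; `NULL` gives a single region tagged 1.
#' @return A [mesh] of `6 * nx * ny * nz` tetrahedra.
#' @export
box_tet_mesh <- function(nx, ny, nz, h = 1, label_planes = NULL) {
  gx <- 0:nx; gy <- 0:ny; gz <- 0:nz
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz)) * h
  dimnames(pts) <- NULL
  vid <- function(x, y, z) 1L + x + (nx + 1L) * (y + (ny + 1L) * z)

  cubes <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1), z = 0:(nz - 1)))
  ncube <- nrow(cubes)
  conn <- matrix(0L, ncube * 6L, 4L)
  for (t in seq_len(6)) {
    vt <- kuhn_tets[[t]]
    for (j in seq_len(4)) {
      conn[seq_len(ncube) + (t - 1L) * ncube, j] <-
        vid(cubes[, 1] + vt[j, 1], cubes[, 2] + vt[j, 2], cubes[, 3] + vt[j, 3])
    }
  }
  tags <- rep(1L, nrow(conn))
  if (!is.null(label_planes)) {
    ax <- match(label_planes$axis, c("x", "y", "z"))
    if (is.na(ax)) mt_usage_error("label_planes$axis must be x, y or z")
    cen_ax <- (pts[conn[, 1], ax] + pts[conn[, 2], ax] +
               pts[conn[, 3], ax] + pts[conn[, 4], ax]) / 4
    tags <- 1L + as.integer(rowSums(outer(cen_ax, label_planes$at, `>`)))
  }
  mesh(pts, conn, tags = tags, reorient = FALSE)
}

#' Two-label ball: spherical tissue shell with enclosed cavity
#'
#' A tetrahedralized ball of two concentric regions emulating ventricular
#' tissue enclosing a blood pool: elements whose centroid lies within
#' `radius_inner` carry the cavity tag (1), the rest the tissue tag (2).
#' Built by warping a structured cube grid onto the ball (no external mesher):
#' each vertex `p` of the cube `[-1, 1]^3` is mapped radially so that its
#' max-norm shell lands on the sphere of the corresponding radius.
#'
#' @param radius_outer,radius_inner outer (tissue) and inner (cavity) radii.
#' @param refinement cubes per axis across the diameter (even; default 10).
#' @return A [mesh] of tetrahedra with tags 1 (cavity) and 2 (tissue).
#' @export
shell_with_cavity <- function(radius_outer = 1, radius_inner = 0.55,
                              refinement = 10) {
  stopifnot(radius_inner < radius_outer, refinement >= 4)
  box <- box_tet_mesh(refinement, refinement, refinement, h = 2 / refinement)
  p <- box$points - 1  # -> [-1, 1]^3
  linf <- pmax(abs(p[, 1]), abs(p[, 2]), abs(p[, 3]))
  l2 <- row_norms(p)
  fac <- ifelse(l2 == 0, 0, linf / l2) * radius_outer
  pts <- p * fac
  m <- mesh(pts, box$conn, tags = box$tags, reorient = FALSE)
  cen <- elem_centroids(m)
  m$tags <- ifelse(row_norms(cen) < radius_inner, 1L, 2L)
  m
}

#' Closed rod ("coil") surface
#'
#' A closed, outward-oriented triangulated cylinder with end caps, emulating
#' a CAD-originated device surface (e.g. a defibrillation coil placed in a
#' blood pool).  Axis along z from 0 to `length`.
#'
#' @param length rod length.
#' @param radius rod radius.
#' @param segments circumferential segments (also used along the axis,
#'   scaled to keep triangles roughly isotropic).
#' @return `list(points = <n x 3>, surface = <mesh_surface>)`.
#' @export
rod_surface <- function(length = 4, radius = 0.5, segments = 16) {
  stopifnot(segments >= 3)
  nax <- max(2L, ceiling(length / (2 * pi * radius / segments)))
  theta <- 2 * pi * (0:(segments - 1)) / segments
  zs <- seq(0, length, length.out = nax + 1)
  ring <- cbind(radius * cos(theta), radius * sin(theta))
  pts <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  nring <- segments
  rid <- function(i, j) (i - 1L) * nring + ((j - 1L) %% nring) + 1L  # ring i, slot j
  faces <- list()
  for (i in seq_len(nax)) {
    j <- seq_len(nring)
    # outward orientation: counter-clockwise seen from outside
    faces[[2 * i - 1]] <- cbind(rid(i, j), rid(i, j + 1), rid(i + 1, j))
    faces[[2 * i]]     <- cbind(rid(i + 1, j), rid(i, j + 1), rid(i + 1, j + 1))
  }
  cb <- nrow(pts) + 1L  # bottom cap centre
  ct <- nrow(pts) + 2L  # top cap centre
  pts <- rbind(pts, c(0, 0, 0), c(0, 0, length))
  j <- seq_len(nring)
  faces[[length(faces) + 1]] <- cbind(cb, rid(1, j + 1), rid(1, j))
  faces[[length(faces) + 1]] <- cbind(ct, rid(nax + 1, j), rid(nax + 1, j + 1))
  list(points = pts, surface = surface(do.call(rbind, faces), nrow(pts)))
}

#' Icosphere triangle mesh
#'
#' Subdivided icosahedron projected onto the sphere; outward-oriented
#' triangles.  The canonical smooth closed test surface for shrinkage-free
#' smoothing.
#'
#' @param refinement number of 4-way subdivision rounds (level 4 gives 2562
#'   vertices).
#' @param radius sphere radius.
#' @return A triangle-only [mesh] (tag 1).
#' @export
icosphere <- function(refinement = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- normalize_rows(v)
  for (lvl in seq_len(refinement)) {
    nv <- nrow(v)
    ek <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- edge_keys(ek, nv)
    ukey <- sort(unique(key))
    mid_of <- match(key, ukey) + nv
    ue <- ek[match(ukey, key), , drop = FALSE]
    mids <- normalize_rows((v[ue[, 1], ] + v[ue[, 2], ]) / 2)
    v <- rbind(v, mids)
    nf <- nrow(f)
    mab <- mid_of[seq_len(nf)]
    mbc <- mid_of[nf + seq_len(nf)]
    mca <- mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], mab, mca), cbind(f[, 2], mbc, mab),
               cbind(f[, 3], mca, mbc), cbind(mab, mbc, mca))
  }
  mesh(v * radius, f, tags = 1L)
}

#' Add seeded Gaussian jitter to mesh vertices
#'
#' Displaces every vertex except corner (POINT-class) vertices by independent
#' Gaussian noise — the "rough interfaces before smoothing" fixture.  Uses a
#' private RNG stream so the caller's random state is untouched.
#'
#' @param m a [mesh].
#' @param sigma displacement standard deviation per coordinate.
#' @param seed integer seed; the same seed reproduces the same jitter.
#' @param labeling optional precomputed [decompose_manifolds()] labeling;
#'   computed at default settings when absent.
#' @return The jittered [mesh].
#' @export
jitter_mesh <- function(m, sigma, seed = 1L, labeling = NULL) {
  if (sigma == 0) return(m)
  if (is.null(labeling)) labeling <- decompose_manifolds(m)
  movable <- labeling$vertex_class != "POINT"
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(3 * sum(movable), sd = sigma), ncol = 3)
  m$points[movable, ] <- m$points[movable, , drop = FALSE] + noise
  m
}
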