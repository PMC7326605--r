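# Tetrahedron quality metrics and reports.
#
# Both metrics are scale-invariant, live on [0, 1] and score the regular
# tetrahedron exactly 1; 0 is a degenerate element.

# sine of the regular tetrahedron's dihedral angle (70.5288...°)
REGULAR_TET_DIHEDRAL_SINE <- 2 * sqrt(2) / 3

# Vectorised core: conn k x 4 over points.
volume_edge_ratios <- function(points, conn) {
  v <- abs(tet_volumes(points, conn))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  l2 <- 0
  for (r in seq_len(6)) {
    d <- points[conn[, pairs[r, 1]], , drop = FALSE] -
         points[conn[, pairs[r, 2]], , drop = FALSE]
    l2 <- l2 + rowSums(d * d)
  }
  lrms3 <- (l2 / 6)^1.5
  q <- ifelse(lrms3 > 0, 6 * sqrt(2) * v / lrms3, 0)
  pmin(pmax(q, 0), 1)
}

min_dihedral_sines <- function(points, conn) {
  v <- abs(tet_volumes(points, conn))
  # faces opposite local vertices 4,3,1,2 listed so that edge (i,j) is
  # shared by the two faces not containing... enumerate explicitly:
  # local faces: f1=(1,2,3), f2=(1,2,4), f3=(1,3,4), f4=(2,3,4)
  areas <- matrix(0, nrow(conn), 4)
  flocal <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (f in seq_len(4)) {
    nrm <- cross3(points[conn[, flocal[f, 2]], , drop = FALSE] -
                  points[conn[, flocal[f, 1]], , drop = FALSE],
                  points[conn[, flocal[f, 3]], , drop = FALSE] -
                  points[conn[, flocal[f, 1]], , drop = FALSE])
    areas[, f] <- row_norms(nrm) / 2
  }
  # edge (local pair) -> the two adjacent local faces
  eadj <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  s <- rep(Inf, nrow(conn))
  for (r in seq_len(6)) {
    l <- row_norms(points[conn[, pairs[r, 1]], , drop = FALSE] -
                   points[conn[, pairs[r, 2]], , drop = FALSE])
    a1 <- areas[, eadj[[r]][1]]; a2 <- areas[, eadj[[r]][2]]
    sr <- ifelse(a1 > 0 & a2 > 0, 3 * v * l / (2 * a1 * a2), 0)
    s <- pmin(s, sr)
  }
  pmin(pmax(s / REGULAR_TET_DIHEDRAL_SINE, 0), 1)
}

#' Volume-edge ratio quality of a tetrahedron
#'
#' `q = 6 sqrt(2) |V| / l_rms^3` where `l_rms` is the root mean square of the
#' six edge lengths; 1 for the regular tetrahedron, 0 when degenerate.
#'
#' @param p0,p1,p2,p3 numeric length-3 coordinates.
#' @return Quality in `[0, 1]`.
#' @export
volume_edge_ratio <- function(p0, p1, p2, p3) {
  unname(volume_edge_ratios(rbind(p0, p1, p2, p3, deparse.level = 0),
                            rbind(1:4)))
}

#' Minimal dihedral sine quality of a tetrahedron
#'
#' Minimum over the six dihedral angles of `sin(theta)`, normalised by the
#' regular tetrahedron's dihedral sine so the regular tet scores 1; clipped
#' to `[0, 1]`, 0 when degenerate.  Uses the identity
#' `sin(theta_e) = 3 V l_e / (2 A_1 A_2)` over the two faces adjacent to
#' edge `e`.
#'
#' @inheritParams volume_edge_ratio
#' @return Quality in `[0, 1]`.
#' @export
min_dihedral_sine <- function(p0, p1, p2, p3) {
  unname(min_dihedral_sines(rbind(p0, p1, p2, p3, deparse.level = 0),
                            rbind(1:4)))
}

elem_quality <- function(points, conn, metric) {
  switch(metric,
         volume_edge_ratio = volume_edge_ratios(points, conn),
         min_dihedral_sine = min_dihedral_sines(points, conn),
         mt_usage_error("unknown quality metric '%s'", metric))
}

#' Element quality report for a tetrahedral mesh
#'
#' Per-tetrahedron quality, min/mean and a histogram over uniform bins of
#' `[0, 1]` — the standard before/after artifact of quality-aware smoothing
#' and re-sampling.
#'
#' @param m a [mesh] containing at least one tetrahedron.
#' @param metric `"volume_edge_ratio"` (default) or `"min_dihedral_sine"`.
#' @param bins number of uniform histogram bins on `[0, 1]`.
#' @return An object of class `quality_report`: `per_elem`, `min`, `mean`,
#'   `histogram` (counts), `breaks`, `metric`.
#' @export
quality_report <- function(m, metric = c("volume_edge_ratio",
                                         "min_dihedral_sine"), bins = 20L) {
  metric <- match.arg(metric)
  tet <- which(m$etype == 4L)
  if (length(tet) == 0)
    mt_geometry_error("quality report requires a tetrahedral mesh")
  q <- elem_quality(m$points, m$conn[tet, , drop = FALSE], metric)
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(q, breaks, rightmost.closed = TRUE), 1L), bins)
  structure(list(per_elem = q, min = min(q), mean = mean(q),
                 histogram = tabulate(idx, nbins = bins), breaks = breaks,
                 metric = metric),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report (%s): %d tets, min %.4f, mean %.4f\n",
              x$metric, length(x$per_elem), x$min, x$mean))
  invisible(x)
}
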