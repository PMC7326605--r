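# Mesh re-sampling by iterative edge bisection and guarded edge collapse.
#
# Resolution change runs in two phases: first every edge longer than the
# maximum threshold is bisected (longest first, conformity maintained by
# subdividing all incident elements), then every edge shorter than the
# minimum threshold is collapsed (shortest first).  A collapse is dismissed
# when it would invert an element, drop its quality below the floor, rotate
# a boundary/interface face normal beyond the allowed shape change, violate
# the manifold-class collapse direction, or cross the tag-restriction
# boundary.  Some short edges are therefore legitimately uncollapsible; they
# are reported, never an error.

#' Re-sampling specification
#'
#' @param min_edge collapse edges shorter than this (or `NULL` to skip the
#'   collapse phase).
#' @param max_edge split edges longer than this (or `NULL` to skip the split
#'   phase).
#' @param avg_edge convenience: a target average edge length, translated to
#'   `min_edge = 0.7 * avg`, `max_edge = 1.4 * avg` (bracket chosen so both
#'   phases engage).
#' @param tag_restriction integer tags to restrict re-sampling to, or `NULL`
#'   for the whole mesh.
#' @param normal_change_max_deg maximum acceptable boundary/interface normal
#'   rotation during a collapse (degrees; default 25).
#' @param quality_floor minimum volume-edge ratio a surviving tetrahedron may
#'   have after a collapse (default 0.05).
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(min_edge = NULL, max_edge = NULL, avg_edge = NULL,
                          tag_restriction = NULL,
                          normal_change_max_deg = 25, quality_floor = 0.05) {
  if (!is.null(avg_edge)) {
    if (avg_edge <= 0) mt_usage_error("avg_edge must be > 0")
    min_edge <- 0.7 * avg_edge
    max_edge <- 1.4 * avg_edge
  }
  if (is.null(min_edge) && is.null(max_edge))
    mt_usage_error("at least one of min_edge/max_edge/avg_edge must be set")
  if (!is.null(min_edge) && min_edge <= 0) mt_usage_error("min_edge must be > 0")
  if (!is.null(max_edge) && max_edge <= 0) mt_usage_error("max_edge must be > 0")
  if (!is.null(min_edge) && !is.null(max_edge) && min_edge >= max_edge)
    mt_usage_error("min_edge must be < max_edge")
  if (normal_change_max_deg <= 0 || normal_change_max_deg >= 180)
    mt_usage_error("normal_change_max_deg must be in (0, 180)")
  if (quality_floor < 0 || quality_floor > 1)
    mt_usage_error("quality_floor must be in [0, 1]")
  structure(list(min_edge = min_edge, max_edge = max_edge,
                 tag_restriction = tag_restriction,
                 normal_change_max_deg = normal_change_max_deg,
                 quality_floor = quality_floor),
            class = "resample_spec")
}

# --- mutable working state ------------------------------------------------

rs_state <- function(m, fields = NULL) {
  e <- new.env(parent = emptyenv())
  e$pts <- m$points
  e$conn <- m$conn
  e$etype <- m$etype
  e$tags <- m$tags
  e$fibers <- m$fibers
  e$alive <- rep(TRUE, n_elems(m))
  g <- split(rep(seq_len(n_elems(m)), times = m$etype),
             m$conn[cbind(rep(seq_len(n_elems(m)), times = m$etype),
                          sequence(m$etype))])
  e$v2e <- rep(list(integer(0)), n_points(m))
  e$v2e[as.integer(names(g))] <- g
  e$valive <- rep(TRUE, n_points(m))
  e$fields <- fields
  e
}

rs_mesh <- function(e) {
  keep <- which(e$alive)
  verts <- sort(unique(as.vector(
    e$conn[cbind(rep(keep, times = e$etype[keep]), sequence(e$etype[keep]))])))
  vmap <- integer(nrow(e$pts)); vmap[verts] <- seq_along(verts)
  conn <- e$conn[keep, , drop = FALSE]
  tri <- e$etype[keep] == 3L
  conn[!tri, ] <- matrix(vmap[conn[!tri, ]], ncol = 4)
  conn[tri, 1:3] <- matrix(vmap[conn[tri, 1:3]], ncol = 3)
  out <- mesh(e$pts[verts, , drop = FALSE], conn, tags = e$tags[keep],
              fibers = if (!is.null(e$fibers)) e$fibers[keep, , drop = FALSE],
              reorient = FALSE)
  fields <- NULL
  if (!is.null(e$fields))
    fields <- lapply(e$fields, function(f) {
      if (f$attachment == "node") data_field(f$values[verts, , drop = FALSE], "node")
      else data_field(f$values[keep, , drop = FALSE], "element")
    })
  list(mesh = out, fields = fields)
}

rs_live_edges <- function(e) {
  keep <- which(e$alive)
  ei <- elem_edge_instances(e$conn[keep, , drop = FALSE], e$etype[keep])
  lo <- pmin(ei$edges[, 1], ei$edges[, 2])
  hi <- pmax(ei$edges[, 1], ei$edges[, 2])
  key <- tuple_key(cbind(lo, hi), nrow(e$pts) + 1)
  first <- match(sort(unique(key)), key)
  cbind(lo[first], hi[first], deparse.level = 0)
}

rs_grow_points <- function(e, k = 1L) {
  nr <- nrow(e$pts)
  e$pts <- rbind(e$pts, matrix(0, k, 3))
  e$v2e <- c(e$v2e, rep(list(integer(0)), k))
  e$valive <- c(e$valive, rep(TRUE, k))
  if (!is.null(e$fields))
    e$fields <- lapply(e$fields, function(f) {
      if (f$attachment == "node")
        f$values <- rbind(f$values, matrix(0, k, f$width))
      f
    })
  nr + seq_len(k)
}

rs_add_elem <- function(e, verts, type, tag, fiber) {
  row <- c(verts, rep(NA_integer_, 4L - length(verts)))
  e$conn <- rbind(e$conn, row)
  e$etype <- c(e$etype, type)
  e$tags <- c(e$tags, tag)
  if (!is.null(e$fibers)) e$fibers <- rbind(e$fibers, fiber)
  e$alive <- c(e$alive, TRUE)
  id <- nrow(e$conn)
  for (v in verts) e$v2e[[v]] <- c(e$v2e[[v]], id)
  if (!is.null(e$fields))
    e$fields <- lapply(e$fields, function(f) {
      # placeholder row; the caller copies the parent's value in
      if (f$attachment == "element") f$values <- rbind(f$values, 0)
      f
    })
  id
}

rs_kill_elem <- function(e, id) {
  e$alive[id] <- FALSE
  vs <- e$conn[id, seq_len(e$etype[id])]
  for (v in vs) e$v2e[[v]] <- e$v2e[[v]][e$v2e[[v]] != id]
}

# elements incident to both a and b (live)
rs_edge_elems <- function(e, a, b) {
  ids <- intersect(e$v2e[[a]], e$v2e[[b]])
  ids[e$alive[ids]]
}

rs_in_restriction <- function(e, ids, restr) {
  if (is.null(restr)) return(TRUE)
  all(e$tags[ids] %in% restr)
}

rs_touches_restriction <- function(e, v, restr) {
  if (is.null(restr)) return(TRUE)
  ids <- e$v2e[[v]]; ids <- ids[e$alive[ids]]
  any(e$tags[ids] %in% restr)
}

# --- split phase ----------------------------------------------------------

rs_split_edge <- function(e, a, b, elems) {
  mid <- rs_grow_points(e, 1L)
  e$pts[mid, ] <- (e$pts[a, ] + e$pts[b, ]) / 2
  if (!is.null(e$fields))
    e$fields <- lapply(e$fields, function(f) {
      if (f$attachment == "node")
        f$values[mid, ] <- (f$values[a, ] + f$values[b, ]) / 2
      f
    })
  for (id in elems) {
    k <- e$etype[id]
    vs <- e$conn[id, seq_len(k)]
    fib <- if (!is.null(e$fibers)) e$fibers[id, ] else NULL
    child1 <- vs; child1[child1 == b] <- mid
    child2 <- vs; child2[child2 == a] <- mid
    tag <- e$tags[id]
    rs_kill_elem(e, id)
    c1 <- rs_add_elem(e, child1, k, tag, fib)
    c2 <- rs_add_elem(e, child2, k, tag, fib)
    if (!is.null(e$fields))
      e$fields <- lapply(e$fields, function(f) {
        if (f$attachment == "element") {
          f$values[c1, ] <- f$values[id, ]
          f$values[c2, ] <- f$values[id, ]
        }
        f
      })
  }
  mid
}

rs_split_phase <- function(e, spec) {
  max_edge <- spec$max_edge
  n_splits <- 0L
  repeat {
    ue <- rs_live_edges(e)
    len <- edge_lengths(e$pts, ue)
    long <- which(len > max_edge)
    if (length(long) == 0) break
    ord <- long[order(-len[long], ue[long, 1], ue[long, 2])]
    did <- FALSE
    for (i in ord) {
      a <- ue[i, 1]; b <- ue[i, 2]
      elems <- rs_edge_elems(e, a, b)
      if (length(elems) == 0) next
      if (!(rs_touches_restriction(e, a, spec$tag_restriction) &&
            rs_touches_restriction(e, b, spec$tag_restriction))) next
      rs_split_edge(e, a, b, elems)
      n_splits <- n_splits + 1L
      did <- TRUE
    }
    if (!did) break
  }
  n_splits
}

# --- collapse phase -------------------------------------------------------

CLASS_RANK <- c(VOLUME = 1L, SURFACE = 2L, LINE = 3L, POINT = 4L)

# boundary/interface face bookkeeping for the shape-preservation check
rs_bfaces <- function(e, labeling) {
  faces <- labeling$patch_faces$faces
  f <- new.env(parent = emptyenv())
  f$faces <- faces
  f$alive <- rep(TRUE, nrow(faces))
  g <- split(rep(seq_len(nrow(faces)), 3L), as.vector(faces))
  f$v2f <- rep(list(integer(0)), nrow(e$pts))
  f$v2f[as.integer(names(g))] <- g
  f
}

rs_bf_grow <- function(bf, nverts) {
  if (length(bf$v2f) < nverts)
    bf$v2f <- c(bf$v2f, rep(list(integer(0)), nverts - length(bf$v2f)))
}

# Attempt to collapse edge (a, b).  Returns TRUE on success.
rs_try_collapse <- function(e, bf, a, b, spec, vclass, vpatch, line_edge_keys) {
  elems_ab <- rs_edge_elems(e, a, b)
  if (length(elems_ab) == 0) return(FALSE)

  ca <- vclass[a]; cb <- vclass[b]
  ra <- CLASS_RANK[[ca]]; rb <- CLASS_RANK[[cb]]
  if (ra == 4L && rb == 4L) return(FALSE)          # two corners: never
  if (ra == rb) {
    if (ca == "SURFACE" && !identical(vpatch[a], vpatch[b])) return(FALSE)
    if (ca == "LINE") {
      # only collapse along a feature line
      k <- tuple_key(cbind(min(a, b), max(a, b)), length(vclass) + 1)
      if (!(k %in% line_edge_keys)) return(FALSE)
    }
    keep <- min(a, b); gone <- max(a, b)
    newpos <- (e$pts[a, ] + e$pts[b, ]) / 2
  } else if (ra < rb) {
    keep <- b; gone <- a; newpos <- e$pts[b, ]
  } else {
    keep <- a; gone <- b; newpos <- e$pts[a, ]
  }

  inc <- unique(c(e$v2e[[a]], e$v2e[[b]]))
  inc <- inc[e$alive[inc]]
  if (!rs_in_restriction(e, inc, spec$tag_restriction)) return(FALSE)
  dying <- elems_ab
  surv <- setdiff(inc, dying)

  # never create an edge above the split threshold
  if (!is.null(spec$max_edge) && length(surv)) {
    nb <- unique(as.vector(
      e$conn[cbind(rep(surv, times = e$etype[surv]), sequence(e$etype[surv]))]))
    nb <- setdiff(nb, c(a, b))
    if (length(nb)) {
      d <- sqrt((e$pts[nb, 1] - newpos[1])^2 + (e$pts[nb, 2] - newpos[2])^2 +
                (e$pts[nb, 3] - newpos[3])^2)
      if (any(d > spec$max_edge)) return(FALSE)
    }
  }

  # simulate surviving elements with `gone` -> `keep` at `newpos`
  if (length(surv)) {
    old_keep <- e$pts[keep, ]
    conn_s <- e$conn[surv, , drop = FALSE]
    conn_s[conn_s == gone] <- keep
    tet_s <- e$etype[surv] == 4L
    e$pts[keep, ] <- newpos
    ok <- TRUE
    if (any(tet_s)) {
      cs <- conn_s[tet_s, , drop = FALSE]
      vol <- tet_volumes(e$pts, cs)
      if (any(vol <= 0)) ok <- FALSE
      if (ok && any(volume_edge_ratios(e$pts, cs) < spec$quality_floor))
        ok <- FALSE
    }
    if (ok && any(!tet_s)) {
      cs <- conn_s[!tet_s, 1:3, drop = FALSE]
      if (any(row_norms(triangle_normals(e$pts, cs, unit = FALSE)) == 0))
        ok <- FALSE
    }
    if (!ok) { e$pts[keep, ] <- old_keep; return(FALSE) }
    e$pts[keep, ] <- old_keep
  }

  # shape preservation: boundary/interface face normal rotation
  rs_bf_grow(bf, nrow(e$pts))
  finc <- unique(c(bf$v2f[[a]], bf$v2f[[b]]))
  finc <- finc[bf$alive[finc]]
  fdying <- integer(0)
  if (length(finc)) {
    fc <- bf$faces[finc, , drop = FALSE]
    has_a <- rowSums(fc == a) > 0; has_b <- rowSums(fc == b) > 0
    fdying <- finc[has_a & has_b]
    fsurv <- finc[!(has_a & has_b)]
    if (length(fsurv)) {
      fc_old <- bf$faces[fsurv, , drop = FALSE]
      n_old <- triangle_normals(e$pts, fc_old)
      fc_new <- fc_old
      fc_new[fc_new == gone] <- keep
      old_keep <- e$pts[keep, ]
      e$pts[keep, ] <- newpos
      n_new_raw <- triangle_normals(e$pts, fc_new, unit = FALSE)
      degen <- row_norms(n_new_raw) == 0
      n_new <- normalize_rows(n_new_raw)
      ang <- normal_angle_deg(n_old, n_new)
      e$pts[keep, ] <- old_keep
      if (any(degen) || any(ang > spec$normal_change_max_deg)) return(FALSE)
    }
  }

  # commit
  e$pts[keep, ] <- newpos
  for (id in dying) rs_kill_elem(e, id)
  surv <- surv[e$alive[surv]]
  for (id in surv) {
    k <- e$etype[id]
    vs <- e$conn[id, seq_len(k)]
    if (gone %in% vs) {
      vs[vs == gone] <- keep
      e$conn[id, seq_len(k)] <- vs
      e$v2e[[keep]] <- c(e$v2e[[keep]], id)
    }
  }
  e$v2e[[gone]] <- integer(0)
  e$valive[gone] <- FALSE
  # faces
  for (id in fdying) {
    vs <- bf$faces[id, ]
    bf$alive[id] <- FALSE
    for (v in vs) bf$v2f[[v]] <- bf$v2f[[v]][bf$v2f[[v]] != id]
  }
  fmove <- bf$v2f[[gone]]
  for (id in fmove) {
    vs <- bf$faces[id, ]
    vs[vs == gone] <- keep
    bf$faces[id, ] <- vs
    bf$v2f[[keep]] <- unique(c(bf$v2f[[keep]], id))
  }
  bf$v2f[[gone]] <- integer(0)
  TRUE
}

rs_collapse_phase <- function(e, spec, labeling) {
  vclass <- labeling$vertex_class
  vpatch <- labeling$patch_id
  le <- labeling$line_edges
  line_edge_keys <- if (nrow(le)) tuple_key(cbind(pmin(le[, 1], le[, 2]),
                                                  pmax(le[, 1], le[, 2])),
                                            length(vclass) + 1) else numeric(0)
  bf <- rs_bfaces(e, labeling)
  n_collapsed <- 0L
  repeat {
    ue <- rs_live_edges(e)
    len <- edge_lengths(e$pts, ue)
    short <- which(len < spec$min_edge)
    if (length(short) == 0) break
    ord <- short[order(len[short], ue[short, 1], ue[short, 2])]
    did <- FALSE
    for (i in ord) {
      a <- ue[i, 1]; b <- ue[i, 2]
      if (!e$valive[a] || !e$valive[b]) next
      if (sqrt(sum((e$pts[a, ] - e$pts[b, ])^2)) >= spec$min_edge) next
      if (rs_try_collapse(e, bf, a, b, spec, vclass, vpatch, line_edge_keys)) {
        n_collapsed <- n_collapsed + 1L
        did <- TRUE
      }
    }
    if (!did) break
  }
  ue <- rs_live_edges(e)
  len <- edge_lengths(e$pts, ue)
  restr_ok <- if (is.null(spec$tag_restriction)) rep(TRUE, nrow(ue)) else
    vapply(seq_len(nrow(ue)), function(i) {
      ids <- unique(c(e$v2e[[ue[i, 1]]], e$v2e[[ue[i, 2]]]))
      ids <- ids[e$alive[ids]]
      all(e$tags[ids] %in% spec$tag_restriction)
    }, logical(1))
  list(n_collapsed = n_collapsed,
       uncollapsible = sum(len < spec$min_edge & restr_ok))
}

# --- public operations ----------------------------------------------------

#' Split all edges longer than a maximum length
#'
#' Repeatedly bisects the currently longest eligible edge at its midpoint,
#' re-subdividing every incident element (tet -> 2 tets, triangle -> 2
#' triangles, so conformity is maintained even across the tag-restriction
#' boundary), until no eligible edge exceeds `max_edge`.  Children inherit
#' the parent's tag and fiber; node data fields are midpoint-interpolated.
#'
#' @param m a [mesh].
#' @param spec a [resample_spec()] with `max_edge` set.
#' @param fields optional list of [data_field()]s to carry through.
#' @return The refined [mesh], or `list(mesh, fields)` when `fields` given.
#' @export
split_long_edges <- function(m, spec, fields = NULL) {
  if (is.null(spec$max_edge)) mt_usage_error("spec$max_edge must be set")
  if (!is.null(fields)) for (f in fields) validate_field(f, m)
  e <- rs_state(m, fields)
  rs_split_phase(e, spec)
  out <- rs_mesh(e)
  if (is.null(fields)) out$mesh else out
}

#' Collapse all edges shorter than a minimum length, where possible
#'
#' Processes edges shorter than `min_edge` in ascending length order.  A
#' collapse merges one endpoint into the other (the lower manifold class
#' moves into the higher: VOLUME into SURFACE into LINE into POINT; equal
#' classes on the same patch collapse to the midpoint; two POINT endpoints
#' never collapse) and deletes the incident degenerate elements.  Attempts
#' are dismissed when a surviving tetrahedron would invert or fall below the
#' quality floor, when a boundary/interface normal would rotate beyond
#' `normal_change_max_deg`, or when the edge crosses the tag-restriction
#' boundary.  Remaining short edges are reported, not an error.
#'
#' @param m a [mesh].
#' @param spec a [resample_spec()] with `min_edge` set.
#' @param labeling optional precomputed [decompose_manifolds()].
#' @return `list(mesh, n_collapsed, uncollapsible)`.
#' @export
collapse_short_edges <- function(m, spec, labeling = NULL) {
  if (is.null(spec$min_edge)) mt_usage_error("spec$min_edge must be set")
  labeling <- labeling %||% decompose_manifolds(m)
  e <- rs_state(m)
  res <- rs_collapse_phase(e, spec, labeling)
  out <- rs_mesh(e)
  list(mesh = out$mesh, n_collapsed = res$n_collapsed,
       uncollapsible = res$uncollapsible)
}

#' Re-sample a mesh to a target edge-length range
#'
#' Runs the split phase (edges above `max_edge` bisected) followed by the
#' collapse phase (edges below `min_edge` collapsed where quality and shape
#' guards allow), and reports edge-length statistics, quality histograms
#' before/after and the uncollapsible-edge count.
#'
#' @param m a [mesh].
#' @param spec a [resample_spec()].
#' @return `list(mesh = <mesh>, report = <resample_report>)`.
#' @export
resample_mesh <- function(m, spec) {
  stat <- function(mm) {
    ue <- mesh_graph(mm)$unique_edges
    len <- edge_lengths(mm$points, ue)
    c(min = min(len), mean = mean(len), max = max(len))
  }
  before <- stat(m)
  q_before <- if (any(m$etype == 4L)) quality_report(m) else NULL
  out <- m
  n_splits <- 0L
  if (!is.null(spec$max_edge)) {
    e <- rs_state(m)
    n_splits <- rs_split_phase(e, spec)
    out <- rs_mesh(e)$mesh
  }
  n_collapsed <- 0L; uncollapsible <- 0L
  if (!is.null(spec$min_edge)) {
    res <- collapse_short_edges(out, spec)
    out <- res$mesh
    n_collapsed <- res$n_collapsed
    uncollapsible <- res$uncollapsible
  }
  q_after <- if (any(out$etype == 4L)) quality_report(out) else NULL
  report <- structure(list(
    edge_before = before, edge_after = stat(out),
    n_elems_before = n_elems(m), n_elems_after = n_elems(out),
    n_splits = n_splits, n_collapsed = n_collapsed,
    uncollapsible = uncollapsible,
    quality_before = q_before, quality_after = q_after),
    class = "resample_report")
  list(mesh = out, report = report)
}

#' @export
print.resample_report <- function(x, ...) {
  cat(sprintf("resample_report: %d -> %d elements (%d splits, %d collapses, %d uncollapsible short edges)\n",
              x$n_elems_before, x$n_elems_after, x$n_splits, x$n_collapsed,
              x$uncollapsible))
  cat(sprintf("  edge length  before: min %.4g mean %.4g max %.4g\n",
              x$edge_before["min"], x$edge_before["mean"], x$edge_before["max"]))
  cat(sprintf("               after:  min %.4g mean %.4g max %.4g\n",
              x$edge_after["min"], x$edge_after["mean"], x$edge_after["max"]))
  if (!is.null(x$quality_after))
    cat(sprintf("  quality mean before %.3f -> after %.3f\n",
                x$quality_before$mean, x$quality_after$mean))
  invisible(x)
}
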